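#' Simulation parameters
#'
#' Settings for the synthetic-locus read simulators. The defaults reproduce
#' the study conditions for this kind of locus: 35-bp error-free tiles from
#' both strands at phred 30 for the positive control, and ancient-DNA-like
#' single-end reads of 36-70 bp whose lengths mostly fall in the 40-60 bp
#' range, with a configurable per-base substitution error rate.
#'
#' @param tile_read_length Tile length in bp for the positive control
#'   (default 35).
#' @param tile_quality Constant phred quality assigned to simulated reads
#'   (default 30).
#' @param ancient_length_range Inclusive bp range of ancient read lengths
#'   (default 36-70).
#' @param ancient_length_mode Inclusive bp range holding most read lengths
#'   (default 40-60).
#' @param ancient_mode_weight Probability that a read length is drawn from
#'   `ancient_length_mode` rather than the full range (default 0.7).
#' @param ancient_error_rate Per-base substitution error probability
#'   (default 0.005; must be < 0.1).
#' @param n_ancient_reads Number of ancient reads to draw.
#' @param seed Integer seed controlling all randomness of the draw.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(tile_read_length = 35, tile_quality = 30,
                       ancient_length_range = c(36L, 70L),
                       ancient_length_mode = c(40L, 60L),
                       ancient_mode_weight = 0.7,
                       ancient_error_rate = 0.005,
                       n_ancient_reads = 10000L, seed = 1L) {
  check_scalar_number(tile_read_length, "tile_read_length", lower = 20)
  check_scalar_number(tile_quality, "tile_quality", lower = 0, upper = 93)
  stopifnot(length(ancient_length_range) == 2L,
            ancient_length_range[1] >= 20,
            ancient_length_range[1] <= ancient_length_range[2],
            length(ancient_length_mode) == 2L,
            ancient_length_mode[1] >= ancient_length_range[1],
            ancient_length_mode[2] <= ancient_length_range[2])
  check_scalar_number(ancient_mode_weight, "ancient_mode_weight", 0, 1)
  if (!is.numeric(ancient_error_rate) || ancient_error_rate < 0 ||
      ancient_error_rate >= 0.1) {
    abort("`ancient_error_rate` must lie in [0, 0.1)")
  }
  check_scalar_number(n_ancient_reads, "n_ancient_reads", lower = 1)
  structure(list(tile_read_length = as.integer(tile_read_length),
                 tile_quality = as.integer(tile_quality),
                 ancient_length_range = as.integer(ancient_length_range),
                 ancient_length_mode = as.integer(ancient_length_mode),
                 ancient_mode_weight = ancient_mode_weight,
                 ancient_error_rate = ancient_error_rate,
                 n_ancient_reads = as.integer(n_ancient_reads),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Mapping parameters
#'
#' @param k Seed (k-mer) length for the index; the mapper lowers the
#'   effective seed length automatically when the read set is too short for
#'   the full-sensitivity guarantee at `k` (see the methods vignette).
#' @param max_mismatches Maximum mismatches for a reported hit (<= 5).
#' @param max_hits_reported Hits kept per read after sorting; uniqueness is
#'   classified before truncation.
#' @return A list of class `map_params`.
#' @export
map_params <- function(k = 13L, max_mismatches = 2L, max_hits_reported = 50L) {
  check_scalar_number(k, "k", lower = 8)
  check_scalar_number(max_mismatches, "max_mismatches", lower = 0, upper = 5)
  check_scalar_number(max_hits_reported, "max_hits_reported", lower = 1)
  structure(list(k = as.integer(k), max_mismatches = as.integer(max_mismatches),
                 max_hits_reported = as.integer(max_hits_reported)),
            class = "map_params")
}

#' Variant-caller parameters
#'
#' Defaults are the published cutoffs: a variant requires a frequency of at
#' least 50.01% and read coverage strictly greater than 5. Cross-source
#' conflicts are disregarded when the conflicting alignment has coverage
#' below 8 (source A, e.g. 454) or below 500 (source B, e.g. Illumina).
#'
#' @param min_alt_freq Minimum non-reference base frequency (default 0.5001).
#' @param min_depth Depth must be strictly greater than this (default 5).
#' @param conflict_min_depth_a,conflict_min_depth_b Depth thresholds below
#'   which a conflicting source is considered unreliable (defaults 8, 500).
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(min_alt_freq = 0.5001, min_depth = 5L,
                          conflict_min_depth_a = 8L, conflict_min_depth_b = 500L) {
  if (!(min_alt_freq > 0 && min_alt_freq <= 1)) {
    abort("`min_alt_freq` must lie in (0, 1]")
  }
  check_scalar_number(min_depth, "min_depth", lower = 0)
  structure(list(min_alt_freq = min_alt_freq, min_depth = as.integer(min_depth),
                 conflict_min_depth_a = as.integer(conflict_min_depth_a),
                 conflict_min_depth_b = as.integer(conflict_min_depth_b)),
            class = "caller_params")
}

#' Consensus parameters
#'
#' Majority-rule consensus at the published 51% base-frequency threshold
#' with no ambiguity codes; sites where no base reaches the threshold fall
#' back to `tie_policy`.
#'
#' @param majority_freq Base frequency required to write a base (> 0.5).
#' @param tie_policy `"reference"` (default) or `"first-alphabetical"`.
#' @return A list of class `consensus_params`.
#' @export
consensus_params <- function(majority_freq = 0.51,
                             tie_policy = c("reference", "first-alphabetical")) {
  if (!(majority_freq > 0.5)) abort("`majority_freq` must be > 0.5")
  tie_policy <- match.arg(tie_policy)
  structure(list(majority_freq = majority_freq, tie_policy = tie_policy,
                 no_ambiguity = TRUE),
            class = "consensus_params")
}

#' Sliding-window parameters
#'
#' Published window sizes: 300 bp for coverage tracks, 500 bp for
#' block-identity tracks, 250 bp for dot-plots; deep positive-control sets
#' use a depth > `control_min_depth` convention (default 1000).
#'
#' @param coverage_window,identity_window,dotplot_window Window sizes in bp
#'   (all >= 50).
#' @param control_min_depth Depth threshold used with deep control read
#'   sets (>= 1).
#' @return A list of class `window_params`.
#' @export
window_params <- function(coverage_window = 300L, identity_window = 500L,
                          dotplot_window = 250L, control_min_depth = 1000L) {
  for (w in c(coverage_window, identity_window, dotplot_window)) {
    check_scalar_number(w, "window", lower = 50)
  }
  check_scalar_number(control_min_depth, "control_min_depth", lower = 1)
  structure(list(coverage_window = as.integer(coverage_window),
                 identity_window = as.integer(identity_window),
                 dotplot_window = as.integer(dotplot_window),
                 control_min_depth = as.integer(control_min_depth)),
            class = "window_params")
}

#' Presence-call decision thresholds
#'
#' The published analysis is qualitative; these numeric thresholds turn its
#' two lines of evidence (diagnostic-SNP consistency and unique coverage
#' relative to the simulated control) into a reproducible decision rule.
#' All values are logged in each call's rationale.
#'
#' @param min_depth Minimum read depth at a diagnostic site for it to count
#'   as covered (default 3).
#' @param min_consistent Minimum number of consistent gene-defining sites
#'   for the SNP branch to call presence (default 2).
#' @param max_inconsistent_frac Maximum tolerated fraction of inconsistent
#'   defining sites for the SNP branch (default 0.2).
#' @param cov_frac Present when sample unique coverage reaches this fraction
#'   of the control unique coverage (default 0.5).
#' @param control_floor Control unique coverage (in percent) below which the
#'   coverage branch is uninformative (default 1).
#' @param absent_cov_frac Absence requires sample unique coverage below this
#'   fraction of the control (default 0.25, half the presence bound: a
#'   present gene's reads tile its whole unique span, while allelic variants
#'   of a surviving paralog converging toward a deleted copy produce only a
#'   trickle of stray unique hits) plus no consistent defining site and
#'   adequate overall depth.
#' @return A list of class `presence_thresholds`.
#' @export
presence_thresholds <- function(min_depth = 3L, min_consistent = 2L,
                                max_inconsistent_frac = 0.2, cov_frac = 0.5,
                                control_floor = 1, absent_cov_frac = 0.25) {
  check_scalar_number(min_depth, "min_depth", lower = 1)
  check_scalar_number(min_consistent, "min_consistent", lower = 1)
  check_scalar_number(max_inconsistent_frac, "max_inconsistent_frac", 0, 1)
  check_scalar_number(cov_frac, "cov_frac", 0, 1)
  check_scalar_number(control_floor, "control_floor", 0, 100)
  check_scalar_number(absent_cov_frac, "absent_cov_frac", 0, 1)
  structure(list(min_depth = as.integer(min_depth),
                 min_consistent = as.integer(min_consistent),
                 max_inconsistent_frac = max_inconsistent_frac,
                 cov_frac = cov_frac, control_floor = control_floor,
                 absent_cov_frac = absent_cov_frac),
            class = "presence_thresholds")
}

#' Pipeline configuration
#'
#' Bundles every parameter group plus file paths and verbosity, and
#' serialises to/from a flat `key = value` text file so runs are fully
#' reproducible from a single config.
#'
#' @param sim,map,caller,consensus,windows,thresholds Parameter objects (see
#'   the respective constructors); defaults used when omitted.
#' @param paths Named character vector/list of file paths.
#' @param verbosity One of `"quiet"`, `"normal"`, `"verbose"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_params(), map = map_params(),
                            caller = caller_params(),
                            consensus = consensus_params(),
                            windows = window_params(),
                            thresholds = presence_thresholds(),
                            paths = list(),
                            verbosity = c("normal", "quiet", "verbose")) {
  verbosity <- match.arg(verbosity)
  structure(list(sim = sim, map = map, caller = caller, consensus = consensus,
                 windows = windows, thresholds = thresholds,
                 paths = as.list(paths), verbosity = verbosity),
            class = "pipeline_config")
}

#' Write a pipeline configuration to a flat key = value file
#'
#' @param config A [pipeline_config()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  flat <- c()
  for (grp in c("sim", "map", "caller", "consensus", "windows", "thresholds")) {
    for (nm in setdiff(names(config[[grp]]), "no_ambiguity")) {
      val <- config[[grp]][[nm]]
      flat <- c(flat, sprintf("%s.%s = %s", grp, nm,
                              paste(format(val, scientific = FALSE), collapse = ",")))
    }
  }
  for (nm in names(config$paths)) {
    flat <- c(flat, sprintf("path.%s = %s", nm, config$paths[[nm]]))
  }
  flat <- c(flat, sprintf("verbosity = %s", config$verbosity))
  writeLines(flat, path)
  invisible(path)
}

#' Read a pipeline configuration from a flat key = value file
#'
#' Values are re-validated through the parameter constructors, so an
#' out-of-range edit fails loudly rather than propagating.
#'
#' @param path File written by [write_config()].
#' @return A [pipeline_config()] object.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) abort(sprintf("malformed config line %d: %s",
                              which(bad)[1], lines[which(bad)[1]]))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  get_group <- function(grp, chr_fields = character()) {
    sel <- startsWith(keys, paste0(grp, "."))
    out <- list()
    for (i in which(sel)) {
      nm <- sub(paste0("^", grp, "\\."), "", keys[i])
      parts <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
      out[[nm]] <- if (nm %in% chr_fields) parts else as.numeric(parts)
    }
    out
  }
  sim <- get_group("sim")
  map <- get_group("map")
  caller <- get_group("caller")
  consensus <- get_group("consensus", chr_fields = "tie_policy")
  consensus$no_ambiguity <- NULL
  windows <- get_group("windows")
  thresholds <- get_group("thresholds")
  paths <- as.list(vals[startsWith(keys, "path.")])
  names(paths) <- sub("^path\\.", "", keys[startsWith(keys, "path.")])
  verbosity <- if (any(keys == "verbosity")) vals[keys == "verbosity"][1] else "normal"
  pipeline_config(sim = do.call(sim_params, sim),
                  map = do.call(map_params, map),
                  caller = do.call(caller_params, caller),
                  consensus = do.call(consensus_params, consensus),
                  windows = do.call(window_params, windows),
                  thresholds = do.call(presence_thresholds, thresholds),
                  paths = paths, verbosity = verbosity)
}

# lightweight stderr logger honouring the config verbosity
pl_log <- function(..., verbosity = getOption("paralocus.verbosity", "normal")) {
  if (identical(verbosity, "quiet")) return(invisible(NULL))
  message(sprintf(...))
}
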