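## Run configuration: aggregates every stage's tunable parameters with
## the pipeline defaults, optionally loaded from YAML with explicit
## overrides taking precedence (overrides > file > defaults).

#' Build a validated run configuration
#'
#' @param ... named overrides of the defaults: `mask` (2304), `min_mapq`
#'   (30), `ploidy` (4), `min_identity` (75), `window` (100000 bp),
#'   `margin_threshold` (2.0), `min_segment` (10 windows), `k_list`
#'   (21, 51, 81), `scaled` (1), `motif` ("TTTAGGG"), `min_run` (10 bp),
#'   `n_groups` (number of contact groups; defaults to the simulator's
#'   chromosome count), `seed`, and `sim` (a list of [sim_config()]
#'   overrides for synthetic runs).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(mask = 2304L, min_mapq = 30L, ploidy = 4L,
                   min_identity = 75, window = 100000L,
                   margin_threshold = 2.0, min_segment = 10L,
                   k_list = c(21L, 51L, 81L), scaled = 1L,
                   motif = "TTTAGGG", min_run = 10L, n_groups = NULL,
                   seed = 1L, sim = list())
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1L]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1L]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, overrides)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  assert_scalar_number(cfg$mask, "mask", min = 0)
  assert_scalar_number(cfg$min_mapq, "min_mapq", min = 0)
  if (!is.numeric(cfg$ploidy) || cfg$ploidy < 2) {
    stop("ploidy must be >= 2", call. = FALSE)
  }
  if (cfg$min_identity < 0 || cfg$min_identity > 100) {
    stop("min_identity must be a percentage in [0, 100]", call. = FALSE)
  }
  assert_scalar_number(cfg$window, "window", min = 1)
  assert_scalar_number(cfg$margin_threshold, "margin_threshold", min = 1)
  assert_scalar_number(cfg$min_segment, "min_segment", min = 1)
  if (any(cfg$k_list < 3)) stop("k_list entries must be >= 3",
                                call. = FALSE)
  assert_scalar_number(cfg$scaled, "scaled", min = 1)
  assert_scalar_number(cfg$min_run, "min_run", min = 1)
  if (!is.character(cfg$motif) || !nzchar(cfg$motif)) {
    stop("motif must be a nonempty string", call. = FALSE)
  }
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' @param path path to a YAML file whose keys are [run_config()] fields.
#' @param ... explicit overrides taking precedence over the file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path, ...) {
  file_cfg <- yaml::read_yaml(path)
  if (is.null(file_cfg)) file_cfg <- list()
  cfg <- utils::modifyList(file_cfg, list(...))
  do.call(run_config, cfg)
}
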