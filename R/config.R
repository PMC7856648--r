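# Run configuration and logging.

#' Analysis run configuration
#'
#' Bundles every tunable analysis option with its default: searchlight
#' half-width 2 (the 125-voxel cube), minimum 3 usable voxels, 50% in-mask
#' cube coverage, 5000 permutations, alpha 0.05, tone included in the
#' phonological model, neural similarities negated to dissimilarities for
#' model comparison, and the `k/n` permutation p convention. Unknown keys
#' are rejected; every option is echoed into the run log together with a
#' hash of the configuration.
#'
#' @param ... overrides of the defaults listed above.
#' @return list of class `rsa_config`.
#' @export
rsa_config <- function(...) {
  defaults <- list(
    half_width = 2L,
    min_voxels = 3L,
    min_mask_frac = 0.5,
    n_perm = 5000L,
    perm_seed = 1L,
    alpha = 0.05,
    tone_mode = "include",
    sign_convention = "negate",
    perm_convention = "proportion",
    z_threshold = 3.1,
    visual_normalizer = "union"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "rsa_config")
}

#' Hash of a configuration
#'
#' 32-bit FNV-1a hash of the deparsed option list, stamped into result
#' files so outputs can be matched to the exact configuration.
#'
#' @param config an [rsa_config()].
#' @return 8-hex-digit string.
#' @export
config_hash <- function(config) {
  opts <- config[order(names(config), method = "radix")]  # locale-stable
  fnv1a32(paste(names(opts), vapply(opts, function(x) paste(format(x), collapse = ","),
                                    character(1)), sep = "=", collapse = ";"))
}

#' Write a plain-text run log
#'
#' Echoes every configuration option, the seeds in use and the voxel-index
#' convention (0-based in all logs and CSVs).
#'
#' @param config an [rsa_config()].
#' @param path log file path.
#' @param extra optional named list of additional entries.
#' @export
write_run_log <- function(config, path, extra = list()) {
  lines <- c(
    sprintf("config_hash: %s", config_hash(config)),
    sprintf("%s: %s", names(config),
            vapply(config, function(x) paste(format(x), collapse = ","),
                   character(1))),
    "voxel_index_convention: 0-based, x-fastest",
    if (length(extra)) sprintf("%s: %s", names(extra),
                               vapply(extra, function(x)
                                 paste(format(x), collapse = ","),
                                 character(1)))
  )
  writeLines(lines, path)
  invisible(path)
}
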