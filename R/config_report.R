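#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the pipeline with its default:
#' Ramachandran regions, the minimum helix run (4), the minimum
#' ALPHA_R flank on each side of a motif window (3), the antiparallel
#' arm-angle filter (on, 120 degrees), the inclusive salt-bridge cutoff
#' (4.0 Angstrom), the polar-contact cutoff (3.5 Angstrom), the chain
#' break CA-CA cutoff (4.5 Angstrom), the consensus denominator mode,
#' and the helical-wheel step (100 degrees/residue). Any field can be
#' overridden by name; unknown names are rejected.
#'
#' @param ... named overrides of the defaults.
#' @return named list of class `sil_config`.
#' @export
sil_config <- function(...) {
  cfg <- list(rama_regions = default_rama_regions(),
              min_run = 4L, flank_min = 3L,
              antiparallel = TRUE, axis_min_angle = 120,
              salt_bridge_cutoff = 4.0, polar_cutoff = 3.5,
              ca_break = 4.5, consensus_denominator = "all20",
              degrees_per_residue = 100, max_planarity = NA_real_)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$salt_bridge_cutoff > 0, cfg$polar_cutoff > 0,
            cfg$ca_break > 0, cfg$min_run >= 1, cfg$flank_min >= 0)
  structure(cfg, class = "sil_config")
}

#' Write an analysis result table as TSV or JSON
#'
#' TSV output keeps a stable column order and rounds floating-point
#' columns to one decimal (0.1 Angstrom / 0.1 degree), so reports are
#' diffable across runs. JSON output keeps full precision and re-parses
#' to the same values. An empty result set yields a header-only TSV (or
#' empty JSON array).
#'
#' @param results data.frame from any analysis operation.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @param round_digits decimals for numeric (non-integer) columns in TSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json"),
                         round_digits = 1) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  if (format == "tsv") {
    out <- results
    for (j in seq_along(out))
      if (is.double(out[[j]])) out[[j]] <- round(out[[j]], round_digits)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(results, path, digits = NA, dataframe = "rows",
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
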