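# Assemble per-conjugate results into a two-method DAR comparison table.

#' Build a DAR comparison table
#'
#' Merges intact-MS and UV DAR results by sample into one table, reference
#' (unconjugated antibody) row first with empty shift/DAR cells. Each
#' sample supplies at most one result per method.
#'
#' @param results Named list keyed by sample; each element a list with
#'   optional fields `ms` (an `ms_dar_result`) and `uv` (a
#'   `uv_dar_result`).
#' @param reference Optional list `list(name =, mass_Da =)` describing the
#'   unconjugated antibody row.
#' @return A `dar_table` data frame with columns `sample`,
#'   `measured_mass_Da`, `mass_shift_Da`, `per_drug_mass_Da`, `dar_ms`,
#'   `dar_uv` (full precision; display rounding happens on write).
#' @export
build_dar_table <- function(results, reference = NULL) {
  if (length(results) == 0L) {
    tab <- data.frame(sample = character(), measured_mass_Da = numeric(),
                      mass_shift_Da = numeric(), per_drug_mass_Da = numeric(),
                      dar_ms = numeric(), dar_uv = numeric())
    return(structure(tab, class = c("dar_table", "data.frame")))
  }
  if (is.null(names(results)) || anyDuplicated(names(results)))
    stop_arg("aggregation error: results must be uniquely named by sample")
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    extra <- setdiff(names(r), c("ms", "uv"))
    if (length(extra))
      stop_arg("aggregation error: sample \"%s\" has unknown method \"%s\"",
               nm, extra[1L])
    if (!is.null(r$ms) && !inherits(r$ms, "ms_dar_result"))
      stop_arg("aggregation error: \"%s\" ms entry is not an ms_dar_result", nm)
    if (!is.null(r$uv) && !inherits(r$uv, "uv_dar_result"))
      stop_arg("aggregation error: \"%s\" uv entry is not a uv_dar_result", nm)
    data.frame(sample = nm,
               measured_mass_Da = r$ms$conjugate_mass_Da %||% NA_real_,
               mass_shift_Da = r$ms$mass_shift_Da %||% NA_real_,
               per_drug_mass_Da = r$ms$per_drug_mass_Da %||% NA_real_,
               dar_ms = r$ms$dar %||% NA_real_,
               dar_uv = r$uv$dar %||% NA_real_)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(reference)) {
    ref <- data.frame(sample = reference$name,
                      measured_mass_Da = reference$mass_Da %||% NA_real_,
                      mass_shift_Da = NA_real_, per_drug_mass_Da = NA_real_,
                      dar_ms = NA_real_, dar_uv = NA_real_)
    tab <- rbind(ref, tab)
  }
  rownames(tab) <- NULL
  structure(tab, class = c("dar_table", "data.frame"))
}

#' Agreement between the MS and UV DAR columns
#'
#' Signed per-sample differences `dar_ms - dar_uv` over rows where both
#' methods are present, plus the mean absolute difference.
#'
#' @param table A [build_dar_table()] result.
#' @return A `method_agreement` list with a `differences` data frame
#'   (`sample`, `dar_ms`, `dar_uv`, `difference`) and
#'   `mean_abs_difference`. Empty (with a warning) when no row has both
#'   methods.
#' @export
method_agreement <- function(table) {
  stopifnot(inherits(table, "dar_table"))
  both <- !is.na(table$dar_ms) & !is.na(table$dar_uv)
  if (!any(both)) {
    warning("no rows with both MS and UV DARs; empty agreement summary")
    diffs <- data.frame(sample = character(), dar_ms = numeric(),
                        dar_uv = numeric(), difference = numeric())
    return(structure(list(differences = diffs,
                          mean_abs_difference = NA_real_),
                     class = "method_agreement"))
  }
  d <- table[both, , drop = FALSE]
  diffs <- data.frame(sample = d$sample, dar_ms = d$dar_ms,
                      dar_uv = d$dar_uv,
                      difference = d$dar_ms - d$dar_uv)
  rownames(diffs) <- NULL
  structure(list(differences = diffs,
                 mean_abs_difference = mean(abs(diffs$difference))),
            class = "method_agreement")
}

#' @export
print.method_agreement <- function(x, ...) {
  if (nrow(x$differences) == 0L) {
    cat("<method_agreement> no complete rows\n")
    return(invisible(x))
  }
  cat("<method_agreement> MS - UV differences:\n")
  print(transform(x$differences, difference = round(difference, 2)))
  cat(sprintf("mean |difference|: %.2f\n", x$mean_abs_difference))
  invisible(x)
}

#' Write a DAR table as CSV
#'
#' Two flavours: the machine table keeps full double precision (and
#' round-trips losslessly through [read_dar_table()]); the display table
#' rounds DARs to one decimal and formats masses with thousands separators,
#' mirroring publication style.
#'
#' @param table A [build_dar_table()] result.
#' @param path Output CSV.
#' @param display Write the 1-decimal display flavour (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_dar_table <- function(table, path, display = FALSE) {
  stopifnot(inherits(table, "dar_table"))
  if (display) {
    fmt_mass <- function(x) ifelse(is.na(x), "",
                                   formatC(x, format = "f", digits = 1,
                                           big.mark = ","))
    fmt_dar <- function(x) ifelse(is.na(x), "",
                                  formatC(round(x, 1), format = "f",
                                          digits = 1))
    out <- data.frame(sample = table$sample,
                      measured_mass_Da = fmt_mass(table$measured_mass_Da),
                      mass_shift_Da = fmt_mass(table$mass_shift_Da),
                      per_drug_mass_Da = fmt_mass(table$per_drug_mass_Da),
                      dar_ms = fmt_dar(table$dar_ms),
                      dar_uv = fmt_dar(table$dar_uv))
    write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    out <- as.data.frame(table)
    for (cl in names(out))
      if (is.numeric(out[[cl]]))
        out[[cl]] <- formatC(out[[cl]], format = "g", digits = 17)
    out[out == "NA"] <- ""
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read back a machine-precision DAR table CSV
#'
#' @param path CSV written by [write_dar_table()] with `display = FALSE`.
#' @return A `dar_table`.
#' @export
read_dar_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (cl in setdiff(names(df), "sample"))
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))  # "" cells become NA
  structure(df, class = c("dar_table", "data.frame"))
}
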