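#' Construct an OTU table
#'
#' The central community container: a non-negative integer count matrix with
#' samples as rows and OTUs as columns, a per-sample crop label and a
#' per-OTU taxonomy lineage string (semicolon-delimited ranks, so a phylum
#' token can be extracted).  All downstream functions assume this
#' orientation; it is validated at construction.
#'
#' @param counts numeric matrix, samples x OTUs, non-negative counts.
#'   Row names are sample ids, column names OTU ids.
#' @param crop character or factor of crop labels, one per sample (named by
#'   sample id or in row order).
#' @param taxonomy character vector of lineage strings, one per OTU (named
#'   by OTU id or in column order).  Missing entries are filled with
#'   `"unclassified"`.
#' @return An object of class `rc_otu_table`: a list with elements
#'   `counts`, `crop`, `taxonomy`.
#' @examples
#' m <- matrix(c(10, 30, 60, 5, 5, 90), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("o1", "o2", "o3")))
#' ot <- otu_table(m, crop = c("maize", "maize"))
#' dim(ot)
#' @export
otu_table <- function(counts, crop, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in OTU table", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids in OTU table", call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  if (any(counts != round(counts)))
    stop("counts must be integers", call. = FALSE)

  crop <- as.character(crop)
  if (!is.null(names(crop))) {
    if (!setequal(names(crop), rownames(counts)))
      stop("crop label names do not match sample ids", call. = FALSE)
    crop <- crop[rownames(counts)]
  }
  if (length(crop) != nrow(counts))
    stop("need one crop label per sample", call. = FALSE)
  if (anyNA(crop) || any(!nzchar(crop)))
    stop("every sample needs a crop label", call. = FALSE)
  names(crop) <- rownames(counts)

  if (is.null(taxonomy)) taxonomy <- rep("unclassified", ncol(counts))
  taxonomy <- as.character(taxonomy)
  if (!is.null(names(taxonomy))) {
    if (!setequal(names(taxonomy), colnames(counts)))
      stop("taxonomy names do not match OTU ids", call. = FALSE)
    taxonomy <- taxonomy[colnames(counts)]
  }
  if (length(taxonomy) != ncol(counts))
    stop("need one taxonomy string per OTU", call. = FALSE)
  taxonomy[is.na(taxonomy) | !nzchar(taxonomy)] <- "unclassified"
  names(taxonomy) <- colnames(counts)

  structure(list(counts = counts, crop = crop, taxonomy = taxonomy),
            class = "rc_otu_table")
}

#' @export
dim.rc_otu_table <- function(x) dim(x$counts)

#' @export
print.rc_otu_table <- function(x, ...) {
  cat(sprintf("rc_otu_table: %d samples x %d OTUs\n",
              nrow(x$counts), ncol(x$counts)))
  cat("crops:", paste(sprintf("%s (n=%d)", names(table(x$crop)),
                              table(x$crop)), collapse = ", "), "\n")
  invisible(x)
}

sample_ids <- function(t) rownames(t$counts)
otu_ids <- function(t) colnames(t$counts)

#' Subset an OTU table by samples and/or OTUs
#'
#' @param t an [otu_table()].
#' @param samples,otus character ids or logical/integer indices; `NULL`
#'   keeps everything.
#' @return An `rc_otu_table`.
#' @export
subset_otu_table <- function(t, samples = NULL, otus = NULL) {
  stopifnot(inherits(t, "rc_otu_table"))
  if (is.null(samples)) samples <- seq_len(nrow(t$counts))
  if (is.null(otus)) otus <- seq_len(ncol(t$counts))
  cn <- t$counts[samples, otus, drop = FALSE]
  otu_table(cn, crop = t$crop[rownames(cn)],
            taxonomy = t$taxonomy[colnames(cn)])
}

#' Validate a nutrient table
#'
#' A nutrient table is a data frame with one row per sample, a `sample_id`
#' column, a `crop` column and the thirteen soil physicochemical variables
#' measured in the study: pH (unitless), salt (permille), BD (g cm-3),
#' SWC (%), NH4_N, NO3_N, Olsen_P, Avail_K (mg kg-1), AN, TP, TK, TN,
#' SOC (g kg-1).  The seven variables entering the multi-nutrient cycling
#' index are SOC, TN, TP, TK, Olsen_P, Avail_K and NO3_N.
#'
#' @param df data frame to validate.
#' @return `df` invisibly, with canonical column order, classed
#'   `rc_nutrient_table`.
#' @export
nutrient_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", "crop", nutrient_vars())
  miss <- setdiff(need, names(df))
  mnc_missing <- intersect(miss, mnc_vars())
  if (length(mnc_missing))
    stop("missing MNC variable ", paste(mnc_missing, collapse = ", "),
         call. = FALSE)
  if (length(miss))
    stop("missing nutrient table column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in nutrient table", call. = FALSE)
  num <- df[nutrient_vars()]
  if (anyNA(num))
    stop("missing values are not allowed in a nutrient table", call. = FALSE)
  conc <- setdiff(nutrient_vars(), "pH")
  if (any(as.matrix(df[conc]) < 0))
    stop("negative concentration in nutrient table", call. = FALSE)
  df <- df[c(need, setdiff(names(df), need))]
  class(df) <- c("rc_nutrient_table", "data.frame")
  df
}

#' Canonical nutrient variable names
#'
#' @return Character vector of the thirteen nutrient/physicochemical
#'   variables (`nutrient_vars()`) or the seven MNC component variables
#'   (`mnc_vars()`).
#' @export
nutrient_vars <- function() {
  c("pH", "salt", "BD", "SWC", "NH4_N", "NO3_N", "Olsen_P", "Avail_K",
    "AN", "TP", "TK", "TN", "SOC")
}

#' @rdname nutrient_vars
#' @export
mnc_vars <- function() {
  c("SOC", "TN", "TP", "TK", "Olsen_P", "Avail_K", "NO3_N")
}
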