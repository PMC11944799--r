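# Readers and writers for the external representations the pipeline
# touches: OTU TSV (OTU-by-sample with optional taxonomy column), BIOM
# (via the biomformat package, read-only), nutrient CSV, and network
# export as GraphML / GEXF / edge-list TSV.  TSV is the canonical
# interchange; everything is round-trip tested.

#' Read an OTU table
#'
#' The TSV dialect is an OTU-by-sample matrix: header row of sample ids,
#' first column the OTU id, optional trailing `taxonomy` column.
#' Orientation is auto-detected (a `taxonomy` column, or `sample_ids`
#' matching the header, marks rows as OTUs; `sample_ids` matching the
#' first column marks rows as samples) and normalised to the internal
#' samples x OTUs convention.  BIOM input (classic JSON or HDF5 2.1) is
#' read through the biomformat package.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param crop per-sample crop labels (named by sample id, or a single
#'   label recycled).  Defaults to `"unknown"`; BIOM sample metadata with
#'   a `crop` column overrides it.
#' @param sample_ids optional known sample ids used to resolve orientation.
#' @param orientation `"auto"`, `"otus_as_rows"` or `"samples_as_rows"`.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom"),
                           crop = "unknown", sample_ids = NULL,
                           orientation = c("auto", "otus_as_rows",
                                           "samples_as_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "biom") return(read_otu_biom(path, crop))

  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("malformed OTU TSV: ", path, call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate row id in OTU table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  body <- df[-1]

  tax_col <- which(tolower(names(body)) == "taxonomy")
  taxonomy <- NULL
  if (length(tax_col)) {
    taxonomy <- as.character(body[[tax_col[1]]])
    body <- body[-tax_col]
  }

  num <- as.matrix(body)
  suppressWarnings(storage.mode(num) <- "double")
  if (anyNA(num))
    stop("non-numeric counts in OTU table: ", path, call. = FALSE)
  if (any(num < 0)) stop("negative counts in OTU table: ", path,
                         call. = FALSE)
  rownames(num) <- ids

  rows_are_otus <- switch(orientation,
    otus_as_rows = TRUE,
    samples_as_rows = FALSE,
    auto = {
      if (!is.null(taxonomy)) TRUE
      else if (!is.null(sample_ids) && all(colnames(num) %in% sample_ids)) TRUE
      else if (!is.null(sample_ids) && all(ids %in% sample_ids)) FALSE
      else TRUE  # canonical external form is OTU-by-sample
    })
  counts <- if (rows_are_otus) t(num) else num
  if (rows_are_otus && !is.null(taxonomy)) names(taxonomy) <- ids
  if (is.null(taxonomy)) {
    warning("no taxonomy column in ", basename(path),
            "; filling with 'unclassified'", call. = FALSE)
  }
  if (length(crop) == 1L && is.null(names(crop)))
    crop <- stats::setNames(rep(crop, nrow(counts)), rownames(counts))
  otu_table(counts, crop = crop, taxonomy = taxonomy)
}

read_otu_biom <- function(path, crop) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("BIOM input requires the 'biomformat' package", call. = FALSE)
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # OTUs x samples
  om <- biomformat::observation_metadata(b)
  taxonomy <- NULL
  if (!is.null(om) && length(om)) {
    taxonomy <- vapply(seq_len(nrow(m)), function(i) {
      x <- if (is.data.frame(om)) unlist(om[i, ]) else unlist(om[[i]])
      paste(as.character(x), collapse = ";")
    }, character(1))
    names(taxonomy) <- rownames(m)
  }
  if (is.null(taxonomy))
    warning("no observation metadata in BIOM file; ",
            "taxonomy filled with 'unclassified'", call. = FALSE)
  sm <- try(biomformat::sample_metadata(b), silent = TRUE)
  if (!inherits(sm, "try-error") && is.data.frame(sm) && "crop" %in% names(sm))
    crop <- stats::setNames(as.character(sm$crop), rownames(sm))
  counts <- t(m)
  if (length(crop) == 1L && is.null(names(crop)))
    crop <- stats::setNames(rep(crop, nrow(counts)), rownames(counts))
  otu_table(counts, crop = crop, taxonomy = taxonomy)
}

#' Write an OTU table as TSV
#'
#' Emits the canonical OTU-by-sample TSV with a trailing `taxonomy`
#' column, re-readable by [read_otu_table()].
#'
#' @param t an [otu_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(t, path) {
  stopifnot(inherits(t, "rc_otu_table"))
  m <- t(t$counts)  # OTUs x samples
  df <- data.frame(otu_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$taxonomy <- unname(t$taxonomy[rownames(m)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Accepted header aliases for nutrient CSV columns (matched after
# lower-casing and stripping everything but letters and digits).
nutrient_aliases <- function() {
  ali <- list(
    sample_id = c("sampleid", "sample", "id"),
    crop = c("crop", "croptype", "group"),
    pH = "ph", salt = c("salt", "salinity"), BD = c("bd", "bulkdensity"),
    SWC = c("swc", "soilwatercontent"),
    NH4_N = c("nh4n", "nh4"), NO3_N = c("no3n", "no3"),
    Olsen_P = c("olsenp", "availablep", "ap"),
    Avail_K = c("availk", "availablek", "ak"),
    AN = c("an", "availablen"), TP = "tp", TK = "tk", TN = "tn",
    SOC = c("soc", "organiccarbon"))
  ali
}

squash_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read a nutrient CSV
#'
#' Header names are matched case-insensitively against a documented alias
#' list (e.g. `"NO3--N"` maps to `NO3_N`); see [nutrient_aliases_table()].
#' All thirteen canonical variables are required; missing MNC variables
#' and negative concentrations are hard errors.
#'
#' @param path CSV path.
#' @return A validated [nutrient_table()].
#' @export
read_nutrient_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ali <- nutrient_aliases()
  nm <- names(df)
  for (canon in names(ali)) {
    hit <- which(squash_name(nm) %in% c(squash_name(canon), ali[[canon]]))
    if (length(hit)) nm[hit[1]] <- canon
  }
  names(df) <- nm
  if (!"sample_id" %in% nm) df$sample_id <- paste0("sample", seq_len(nrow(df)))
  if (!"crop" %in% nm) df$crop <- "unknown"
  nutrient_table(df)
}

#' @rdname read_nutrient_table
#' @return `nutrient_aliases_table()`: a data frame mapping canonical
#'   column names to their accepted aliases.
#' @export
nutrient_aliases_table <- function() {
  ali <- nutrient_aliases()
  data.frame(canonical = names(ali),
             aliases = vapply(ali, paste, character(1), collapse = ", "),
             row.names = NULL)
}

#' Write a nutrient table as CSV
#'
#' @param nt a [nutrient_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nutrient_table <- function(nt, path) {
  nt <- nutrient_table(nt)
  utils::write.csv(as.data.frame(nt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a co-occurrence network
#'
#' Nodes carry the OTU id, module assignment and degree; edges carry the
#' signed Spearman r (`r`), its absolute value as `weight`, and the
#' p-value.  GraphML files re-import with [read_network()]; GEXF targets
#' Gephi; `edge_tsv` writes a plain edge list plus a `<path>.nodes.tsv`
#' companion.
#'
#' @param net a `rc_network` from [build_network()].
#' @param path output path.
#' @param format `"graphml"`, `"gexf"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "gexf",
                                                "edge_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "rc_network"))
  g <- net$graph
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edge_tsv") {
    ed <- network_edges(net)
    utils::write.table(ed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nd <- network_nodes(net)
    utils::write.table(nd, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    write_gexf(net, path)
  }
  invisible(path)
}

# Minimal GEXF 1.2 writer (undirected, static); igraph has no GEXF
# backend.  Attribute set mirrors the GraphML export.
write_gexf <- function(net, path) {
  nd <- network_nodes(net)
  ed <- network_edges(net)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">')
  w('  <graph mode="static" defaultedgetype="undirected">')
  w('    <attributes class="node">')
  w('      <attribute id="module" title="module" type="integer"/>')
  w('      <attribute id="degree" title="degree" type="integer"/>')
  w('    </attributes>')
  w('    <attributes class="edge">')
  w('      <attribute id="r" title="r" type="double"/>')
  w('      <attribute id="p" title="p" type="double"/>')
  w('    </attributes>')
  w('    <nodes>')
  for (i in seq_len(nrow(nd)))
    w('      <node id="%s" label="%s"><attvalues><attvalue for="module" value="%d"/><attvalue for="degree" value="%d"/></attvalues></node>',
      esc(nd$otu_id[i]), esc(nd$otu_id[i]), nd$module[i], nd$degree[i])
  w('    </nodes>')
  w('    <edges>')
  if (nrow(ed)) for (i in seq_len(nrow(ed)))
    w('      <edge id="e%d" source="%s" target="%s" weight="%.17g"><attvalues><attvalue for="r" value="%.17g"/><attvalue for="p" value="%.17g"/></attvalues></edge>',
      i, esc(ed$otu_a[i]), esc(ed$otu_b[i]), abs(ed$r[i]), ed$r[i], ed$p[i])
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
  invisible(path)
}

#' Re-import an exported network
#'
#' @param path a GraphML file written by [write_network()].
#' @return A `rc_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- igraph::read_graph(path, format = "graphml")
  as_rc_network(g)
}
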