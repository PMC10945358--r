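#' Construct an OTU table
#'
#' The central container consumed by all network inference: an integer count
#' matrix with taxa as rows and samples as columns, a taxonomy lineage per
#' taxon, and a provenance log recording every processing step applied.
#'
#' @param counts Non-negative integer matrix, taxa x samples, with unique
#'   row (taxon ID) and column (sample ID) names.
#' @param taxonomy Named character vector mapping every taxon ID to a
#'   semicolon-delimited lineage. Taxa without an entry are filled with
#'   `"Unassigned"`.
#' @param provenance Character vector; free-text processing log.
#' @return An object of class `peatnet_otu`.
#' @export
otu_table <- function(counts, taxonomy = NULL, provenance = character()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry taxon row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate taxon IDs in `counts`", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample IDs in `counts`", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  tax <- setNames(rep("Unassigned", nrow(counts)), rownames(counts))
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) {
      stop("`taxonomy` must be a named character vector", call. = FALSE)
    }
    hit <- intersect(names(taxonomy), rownames(counts))
    tax[hit] <- as.character(taxonomy[hit])
  }
  structure(list(counts = counts, taxonomy = tax, provenance = provenance),
            class = "peatnet_otu")
}

#' @export
print.peatnet_otu <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "taxa x", ncol(x$counts), "samples\n")
  cat("Total reads:", sum(x$counts), "\n")
  if (length(x$provenance)) {
    cat("Provenance:\n")
    cat(paste0("  - ", x$provenance, collapse = "\n"), "\n")
  }
  invisible(x)
}

log_step <- function(table, msg) {
  table$provenance <- c(table$provenance, msg)
  table
}

#' Read / write tab-separated OTU tables
#'
#' The on-disk format is a TSV whose first column holds taxon IDs and whose
#' header names the samples. `read_otu_table()` accepts an optional taxonomy
#' TSV (columns: taxon ID, lineage). Round-trips are exact: writing then
#' reading reproduces counts and taxonomy bit-identically.
#'
#' @param path Path of the count TSV.
#' @param taxonomy_path Optional path of the taxonomy TSV.
#' @return A [otu_table()] object.
#' @export
read_otu_table <- function(path, taxonomy_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- as.character(df[[1]])
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) taxonomy <- read_taxonomy(taxonomy_path)
  otu_table(counts, taxonomy,
            provenance = paste0("read ", nrow(counts), " taxa x ",
                                ncol(counts), " samples from ", path))
}

#' @rdname read_otu_table
#' @param table A [otu_table()] object to write.
#' @export
write_otu_table <- function(table, path, taxonomy_path = NULL) {
  stopifnot(inherits(table, "peatnet_otu"))
  df <- data.frame(taxon_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy_path)) {
    write_taxonomy(table$taxonomy, taxonomy_path)
  }
  invisible(path)
}

#' Read / write taxonomy tables
#'
#' Taxonomy TSVs have two columns: taxon ID and a semicolon-delimited
#' lineage. Both Greengenes-style rank prefixes (`d__Bacteria;p__...`) and
#' bare SILVA rank names are accepted downstream.
#'
#' @param path File path.
#' @return A named character vector (taxon ID -> lineage).
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' @rdname read_taxonomy
#' @param taxonomy Named character vector to write.
#' @export
write_taxonomy <- function(taxonomy, path) {
  df <- data.frame(taxon_id = names(taxonomy), taxonomy = unname(taxonomy),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU table from a BIOM file
#'
#' Optional ingestion path for BIOM-format tables via the `biomformat`
#' package; taxonomy is pulled from the observation metadata when present.
#'
#' @param path Path of a BIOM file.
#' @return A [otu_table()] object.
#' @export
read_otu_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("BIOM ingestion requires the `biomformat` package", call. = FALSE)
  }
  b <- biomformat::read_biom(path)
  counts <- as.matrix(biomformat::biom_data(b))
  md <- biomformat::observation_metadata(b)
  taxonomy <- NULL
  if (!is.null(md) && length(md)) {
    lineage <- if (is.data.frame(md)) {
      apply(md, 1L, function(r) paste(r[!is.na(r)], collapse = ";"))
    } else {
      vapply(md, function(r) paste(unlist(r), collapse = ";"), character(1))
    }
    taxonomy <- setNames(lineage, rownames(counts))
  }
  otu_table(counts, taxonomy,
            provenance = paste0("read BIOM table from ", path))
}

#' Read sample metadata
#'
#' Metadata TSV with columns `sample_id`, `site`, `land_use`, `plot`,
#' `depth`. `land_use` and `depth` are validated against their declared
#' levels.
#'
#' @param path File path.
#' @return A data.frame of sample metadata.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("sample_id", "site", "land_use", "plot", "depth")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample IDs in metadata", call. = FALSE)
  }
  bad <- setdiff(unique(df$land_use), c("natural", "cultivated"))
  if (length(bad)) {
    stop("unknown land_use level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read / write soil trait tables
#'
#' Trait TSV: first column `sample_id`, remaining columns numeric traits
#' (CMR, phenolics, carbohydrates, DOC, FTIR ratio, SOC, nutrients, pH ...).
#'
#' @param path File path.
#' @return A data.frame with `sample_id` plus numeric trait columns.
#' @export
read_traits <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_traits
#' @param traits Trait data.frame to write.
#' @export
write_traits <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rarefy samples to a common sequencing depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric draw) to exactly `depth` reads. Samples whose total is
#' below `depth` are dropped and recorded loudly in the provenance log.
#' Deterministic under a fixed seed.
#'
#' @param table A [otu_table()] object.
#' @param depth Target depth per sample (default 39575 reads).
#' @param seed Integer RNG seed.
#' @return A rarefied [otu_table()].
#' @export
rarefy <- function(table, depth = 39575, seed = 1) {
  stopifnot(inherits(table, "peatnet_otu"))
  if (length(depth) != 1L || depth < 1) {
    stop("`depth` must be a single count >= 1", call. = FALSE)
  }
  totals <- colSums(table$counts)
  keep <- totals >= depth
  dropped <- colnames(table$counts)[!keep]
  counts <- table$counts[, keep, drop = FALSE]
  set.seed(seed)
  # vegan::rrarefy expects samples as rows
  at_depth <- totals[keep] == depth
  if (any(!at_depth)) {
    # vegan warns when a table has no singleton counts (a heuristic for
    # "not raw counts"); simulated tables trip it spuriously
    sub <- withCallingHandlers(
      t(vegan::rrarefy(t(counts[, !at_depth, drop = FALSE]), depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    counts[, !at_depth] <- sub
  }
  storage.mode(counts) <- "integer"
  table$counts <- counts
  msg <- paste0("rarefied to ", depth, " reads/sample (seed ", seed, ")")
  if (length(dropped)) {
    msg <- paste0(msg, "; DROPPED ", length(dropped),
                  " sample(s) below depth: ", paste(dropped, collapse = ", "))
    warning("rarefy dropped ", length(dropped),
            " sample(s) with fewer than ", depth, " reads", call. = FALSE)
  }
  log_step(table, msg)
}

#' Remove archaeal taxa
#'
#' Drops every taxon whose lineage's domain rank matches "Archaea",
#' case-insensitively and with or without a `d__`/`k__` prefix. The number
#' of taxa and the fraction of reads removed are logged.
#'
#' @param table A [otu_table()] object with taxonomy.
#' @return The filtered [otu_table()].
#' @export
remove_archaea <- function(table) {
  stopifnot(inherits(table, "peatnet_otu"))
  domain <- vapply(strsplit(table$taxonomy, ";", fixed = TRUE),
                  function(x) trimws(x[1]), character(1))
  domain <- sub("^[dk]__", "", domain, ignore.case = TRUE)
  is_arch <- !is.na(domain) & tolower(domain) == "archaea"
  n_removed <- sum(is_arch)
  read_frac <- if (sum(table$counts) > 0) {
    sum(table$counts[is_arch, , drop = FALSE]) / sum(table$counts)
  } else 0
  table$counts <- table$counts[!is_arch, , drop = FALSE]
  table$taxonomy <- table$taxonomy[rownames(table$counts)]
  log_step(table, sprintf(
    "removed %d archaeal taxa (%.2f%% of reads)", n_removed, 100 * read_frac))
}

#' Keep the most abundant taxa
#'
#' Retains the `n` taxa with the highest total counts across samples
#' (default 2000). Ties at the cutoff are broken by taxon ID in
#' lexicographic order so the selection is deterministic. The fraction of
#' total reads retained is logged.
#'
#' @param table A [otu_table()] object.
#' @param n Number of taxa to keep; if larger than the table, the full
#'   table is returned.
#' @return The filtered [otu_table()].
#' @export
top_abundant <- function(table, n = 2000) {
  stopifnot(inherits(table, "peatnet_otu"))
  if (length(n) != 1L || n < 1) stop("`n` must be >= 1", call. = FALSE)
  totals <- rowSums(table$counts)
  ord <- order(-totals, rownames(table$counts), method = "radix")
  keep_ids <- rownames(table$counts)[ord[seq_len(min(n, length(ord)))]]
  kept_frac <- if (sum(totals) > 0) {
    sum(totals[keep_ids]) / sum(totals)
  } else 1
  table$counts <- table$counts[keep_ids, , drop = FALSE]
  table$taxonomy <- table$taxonomy[keep_ids]
  log_step(table, sprintf(
    "kept top %d taxa by total abundance (%.1f%% of reads retained)",
    length(keep_ids), 100 * kept_frac))
}

#' Per-sample relative abundances
#'
#' Converts counts to fractions that sum to 1 within each sample.
#'
#' @param table A [otu_table()] object; every sample total must be > 0.
#' @return A numeric matrix (taxa x samples) of fractions.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "peatnet_otu"))
  totals <- colSums(table$counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(table$counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(table$counts, 2L, totals, "/")
}
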