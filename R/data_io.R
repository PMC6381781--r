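# Readers and writers for the external artifacts the screen consumes:
# expression matrices, bait lists, BLAST tabular hits, functional-bin maps,
# differential-expression lists and gene annotations. All formats are plain
# tab-separated text.

#' Read a normalized expression matrix
#'
#' Reads a tab-separated gene-by-condition matrix: first row condition IDs,
#' first column gene IDs, remaining cells numeric (log-scale, already
#' normalized upstream, e.g. RMA output). Duplicate gene or condition IDs and
#' non-numeric cells are rejected with an informative error.
#'
#' @param path Path to a TSV file.
#' @param missing_token Text standing for a missing value (default `"NA"`).
#' @param transpose If `TRUE`, the file is conditions-in-rows and is
#'   transposed on read.
#' @return A numeric matrix with gene IDs as row names and condition IDs as
#'   column names; missing cells are `NA`.
#' @seealso [write_expression_matrix()], [missing_fraction()]
#' @export
read_expression_matrix <- function(path, missing_token = "NA", transpose = FALSE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2)
    stop("expression file needs a gene-ID column plus at least one condition column: ", path)
  gene_ids <- tab[[1L]]
  cond_ids <- colnames(tab)[-1L]
  if (anyDuplicated(gene_ids))
    stop("duplicated gene IDs in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cond_ids))
    stop("duplicated condition IDs in ", path, ": ",
         paste(unique(cond_ids[duplicated(cond_ids)]), collapse = ", "))
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  raw[raw == missing_token] <- NA_character_
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at gene '%s', condition '%s': '%s'",
                 gene_ids[bad[1L, 1L]], cond_ids[bad[1L, 2L]],
                 raw[bad[1L, 1L], bad[1L, 2L]]))
  dimnames(num) <- list(gene_ids, cond_ids)
  if (transpose) num <- t(num)
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix to TSV
#'
#' Values are written at full double precision so that a write/read
#' round-trip reproduces the matrix to within floating-point representation.
#'
#' @param m Numeric matrix with gene row names and condition column names.
#' @param path Output path.
#' @param missing_token Text written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, missing_token = "NA") {
  validate_expression_matrix(m)
  body <- apply(m, 1L, function(row) {
    cells <- ifelse(is.na(row), missing_token, sprintf("%.17g", row))
    paste(cells, collapse = "\t")
  })
  lines <- c(paste(c("gene_id", colnames(m)), collapse = "\t"),
             paste(rownames(m), body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression matrix must be a numeric matrix")
  if (nrow(m) < 1L || ncol(m) < 2L)
    stop("expression matrix needs at least 1 gene and 2 conditions")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must carry gene and condition IDs as dimnames")
  if (anyDuplicated(rownames(m))) stop("duplicated gene IDs")
  if (anyDuplicated(colnames(m))) stop("duplicated condition IDs")
  if (any(is.infinite(m))) stop("expression matrix holds non-finite values")
  invisible(m)
}

#' Fraction of missing conditions per gene
#'
#' @param m Expression matrix as returned by [read_expression_matrix()].
#' @return Named numeric vector, one entry per gene.
#' @export
missing_fraction <- function(m) rowMeans(is.na(m))

#' Read a bait-gene list
#'
#' One gene ID per line; blank lines and lines starting with `#` are
#' ignored. Duplicated IDs are collapsed with a warning; a file with no IDs
#' is an error.
#'
#' @param path Path to the list file.
#' @param label Free-text label for the set (e.g. `"lignin biosynthesis"`).
#' @return Character vector of bait IDs in file order, with a `label`
#'   attribute.
#' @export
read_bait_set <- function(path, label = basename(path)) {
  lines <- trimws(readLines(path))
  ids <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(ids) == 0L) stop("bait file holds no gene IDs: ", path)
  if (anyDuplicated(ids)) {
    warning("duplicated bait IDs collapsed: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    ids <- unique(ids)
  }
  structure(ids, label = label)
}

#' Write a bait-gene list
#'
#' @param baits Character vector of bait IDs (optionally with a `label`
#'   attribute, written as a comment header).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bait_set <- function(baits, path) {
  label <- attr(baits, "label")
  header <- if (is.null(label)) character() else paste("#", label)
  writeLines(c(header, as.character(baits)), path)
  invisible(path)
}

blast_columns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read BLAST tabular hits (outfmt 6)
#'
#' Parses the standard 12-column BLAST tabular format. Lines with a wrong
#' column count raise a parse error naming the line.
#'
#' @param path Path to a BLAST `-outfmt 6` file.
#' @return A data frame with the 12 standard columns (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`), rows in file order.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(qseqid = character(), sseqid = character(),
                      pident = double(), length = integer(),
                      mismatch = integer(), gapopen = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = double(), bitscore = double(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("BLAST tabular line ", which(nf != 12L)[1L], " has ",
         nf[nf != 12L][1L], " columns (expected 12): ", path)
  hits <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  colnames(hits) <- blast_columns
  num_int <- c("length", "mismatch", "gapopen", "qstart", "qend", "sstart", "send")
  for (col in num_int) hits[[col]] <- as.integer(hits[[col]])
  for (col in c("pident", "evalue", "bitscore")) hits[[col]] <- as.numeric(hits[[col]])
  if (any(is.na(hits$evalue)) || any(hits$evalue < 0))
    stop("invalid e-value in ", path)
  if (any(hits$pident < 0 | hits$pident > 100))
    stop("percent identity outside [0, 100] in ", path)
  hits
}

#' Write BLAST tabular hits
#'
#' @param hits Data frame as returned by [read_blast_tab()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  stopifnot(all(blast_columns %in% colnames(hits)))
  utils::write.table(hits[, blast_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-to-functional-bin map
#'
#' Two-column TSV with header `gene_id<TAB>bin` (MapMan-style categories).
#' A gene listed on several lines belongs to several bins.
#'
#' @param path Path to the TSV file.
#' @return Named list mapping each gene ID to a character vector of bin
#'   labels.
#' @export
read_bin_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  if (nrow(tab) == 0L) return(structure(list(), names = character()))
  if (ncol(tab) < 2L) stop("bin map needs columns gene_id and bin: ", path)
  lapply(split(tab[[2L]], tab[[1L]]), unique)
}

#' Write a gene-to-functional-bin map
#'
#' @param bins Named list as returned by [read_bin_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_map <- function(bins, path) {
  gene <- rep(names(bins), lengths(bins))
  tab <- data.frame(gene_id = gene, bin = unlist(bins, use.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differentially-expressed gene list
#'
#' TSV with header and columns `gene_id` and optionally `direction`
#' (`up`/`down`), as produced upstream by a DE caller. Duplicate IDs are
#' collapsed.
#'
#' @param path Path to the TSV file.
#' @param label Contrast name (e.g. `"WRKY12-DR internode"`).
#' @return A list with elements `label`, `gene_ids` (character) and
#'   `direction` (named character or `NULL`), of class `"de_list"`.
#' @export
read_de_list <- function(path, label = basename(path)) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  ids <- unique(tab[[1L]])
  direction <- NULL
  if (ncol(tab) >= 2L) {
    direction <- tab[[2L]][!duplicated(tab[[1L]])]
    names(direction) <- ids
  }
  structure(list(label = label, gene_ids = ids, direction = direction),
            class = "de_list")
}

#' Write a differentially-expressed gene list
#'
#' @param de A `"de_list"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_list <- function(de, path) {
  tab <- data.frame(gene_id = de$gene_ids)
  if (!is.null(de$direction)) tab$direction <- unname(de$direction[de$gene_ids])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations
#'
#' TSV with header and columns `gene_id`, `tf_family`, `species`,
#' `display_name`; all but `gene_id` optional. An empty `tf_family` cell
#' means the gene is treated as a non-TF. Annotation is open-world: genes
#' absent from the table are simply unannotated.
#'
#' @param path Path to the TSV file.
#' @return Data frame with one row per gene.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  for (col in c("tf_family", "species", "display_name"))
    if (is.null(tab[[col]])) tab[[col]] <- NA_character_
  tab[tab == ""] <- NA_character_
  if (anyDuplicated(tab$gene_id))
    stop("duplicated gene_id in annotation table: ", path)
  tab[, c("gene_id", "tf_family", "species", "display_name")]
}

#' Write gene annotations
#'
#' @param annotations Data frame as returned by [read_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Collapse probe-level edges to gene level
#'
#' Microarray compendia report probes, not loci; when a probe-to-gene map is
#' available, edges from several probes of the same gene can be collapsed to
#' the probe with the strongest score.
#'
#' @param edges Edge table from [screen_baits()].
#' @param probe_map Named character vector or two-column data frame mapping
#'   probe IDs to gene IDs; unmapped probes keep their own ID.
#' @return Edge table with a `gene` column and, per (bait, gene), only the
#'   maximum-BF probe retained.
#' @export
collapse_probe_edges <- function(edges, probe_map) {
  if (is.data.frame(probe_map)) {
    map <- probe_map[[2L]]
    names(map) <- probe_map[[1L]]
  } else map <- probe_map
  gene <- map[edges$partner]
  gene[is.na(gene)] <- edges$partner[is.na(gene)]
  edges$gene <- unname(gene)
  ord <- order(edges$bait, edges$gene, -edges$bf, edges$partner)
  edges <- edges[ord, , drop = FALSE]
  keep <- !duplicated(edges[, c("bait", "gene")])
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
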