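#' Alignment incidence structure
#'
#' A sparse binary membership matrix linking reads (rows) to
#' (gene, allele) targets (columns) for one cell. Each row records the set
#' of equally-best alignments of one read to the diploid transcriptome;
#' transcripts of the same gene and allele are collapsed into a single
#' target.
#'
#' @param membership Sparse (or dense) binary matrix, reads x targets.
#' @param genes Character vector, gene id of each target column.
#' @param alleles Character vector, `"M"` (maternal) or `"P"` (paternal)
#'   for each target column.
#' @param reads Read identifiers (defaults to membership rownames).
#' @param cell Cell identifier the reads belong to.
#'
#' @return An object of class `alignment_incidence` with elements
#'   `membership` (a `dgCMatrix`), `targets` (data.frame of `gene`,
#'   `allele`), `reads`, and `cell`.
#' @export
alignment_incidence <- function(membership, genes, alleles,
                                reads = rownames(membership),
                                cell = NA_character_) {
  membership <- as(as(membership, "CsparseMatrix"), "dMatrix")
  membership@x[] <- 1
  genes <- as.character(genes)
  alleles <- as.character(alleles)
  if (length(genes) != ncol(membership) || length(alleles) != ncol(membership))
    stop("genes/alleles must have one entry per membership column")
  if (!all(alleles %in% ALLELES))
    stop("alleles must be coded 'M' or 'P'")
  if (anyDuplicated(paste(genes, alleles)))
    stop("duplicate (gene, allele) targets")
  if (nrow(membership) > 0 && any(Matrix::rowSums(membership) < 1))
    stop("every read must have at least one alignment target")
  if (is.null(reads)) reads <- paste0("read", seq_len(nrow(membership)))
  structure(
    list(membership = membership,
         targets = data.frame(gene = genes, allele = alleles,
                              stringsAsFactors = FALSE),
         reads = as.character(reads),
         cell = cell),
    class = "alignment_incidence")
}

#' @export
print.alignment_incidence <- function(x, ...) {
  cat(sprintf("alignment_incidence: %d reads, %d (gene, allele) targets, cell '%s'\n",
              nrow(x$membership), ncol(x$membership), x$cell))
  invisible(x)
}

#' @export
dim.alignment_incidence <- function(x) dim(x$membership)

empty_incidence <- function(cell = NA_character_) {
  alignment_incidence(Matrix::sparseMatrix(i = integer(), j = integer(),
                                           x = numeric(), dims = c(0L, 0L)),
                      genes = character(), alleles = character(),
                      reads = character(), cell = cell)
}

# build an incidence from parallel vectors of (read id, gene, allele),
# collapsing repeated (read, gene, allele) triples (e.g. several
# transcripts of one gene)
incidence_from_hits <- function(read_id, gene, allele, cell = NA_character_) {
  if (length(read_id) == 0) {
    warning("no alignments found; returning empty incidence")
    return(empty_incidence(cell))
  }
  reads <- unique(read_id)
  tkey <- paste(gene, allele, sep = "\r")
  targets <- unique(tkey)
  i <- match(read_id, reads)
  j <- match(tkey, targets)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(reads), length(targets)))
  m@x[] <- 1
  parts <- strsplit(targets, "\r", fixed = TRUE)
  alignment_incidence(m,
                      genes = vapply(parts, `[`, "", 1L),
                      alleles = vapply(parts, `[`, "", 2L),
                      reads = reads, cell = cell)
}

#' Read allele-resolved alignments into an incidence structure
#'
#' Parses either a SAM/BAM file whose reference names carry an allele
#' suffix (e.g. `Gnai3_M` / `Gnai3_P`), or a tab-separated
#' equivalence-class table with lines `read_id<TAB>gene:allele[,...]`.
#' All equally-best alignments of a read form its target set; alignments
#' to several transcripts of one gene and allele collapse to one target.
#'
#' @param path Input file.
#' @param format `"auto"` (by file extension), `"bam"`, `"sam"`, or
#'   `"ec"` (equivalence-class table).
#' @param allele_suffix Named character vector mapping allele codes to
#'   reference-name suffixes; default `c(M = "_M", P = "_P")`.
#' @param tx2gene Optional data.frame with columns `tx`, `gene` mapping
#'   transcript names (after suffix removal) to gene ids.
#' @param cell Cell identifier; defaults to the file base name (one cell
#'   per file, as in SMART-seq protocols).
#'
#' @return An [alignment_incidence()] object.
#' @export
read_alignments <- function(path, format = c("auto", "bam", "sam", "ec"),
                            allele_suffix = c(M = "_M", P = "_P"),
                            tx2gene = NULL, cell = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     bam = "bam", sam = "sam",
                     tsv = "ec", txt = "ec", ec = "ec",
                     stop("cannot infer format from extension of ", path))
  }
  if (is.null(cell)) cell <- sub("\\.[^.]*$", "", basename(path))
  if (format == "ec") return(read_ec_table(path, cell = cell))

  bam <- path
  if (format == "sam")
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  rec <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "rname", "flag")))[[1]]
  keep <- bitwAnd(rec$flag, 4L) == 0L
  qname <- rec$qname[keep]
  rname <- as.character(rec$rname)[keep]
  if (length(qname) == 0) {
    warning("no mapped reads in ", path, "; returning empty incidence")
    return(empty_incidence(cell))
  }
  parsed <- parse_target_names(rname, allele_suffix, tx2gene, context = path)
  incidence_from_hits(qname, parsed$gene, parsed$allele, cell = cell)
}

parse_target_names <- function(rname, allele_suffix, tx2gene = NULL,
                               context = "input") {
  allele <- rep(NA_character_, length(rname))
  base <- rname
  for (a in names(allele_suffix)) {
    suf <- allele_suffix[[a]]
    hit <- endsWith(rname, suf)
    allele[hit] <- a
    base[hit] <- substr(rname[hit], 1L, nchar(rname[hit]) - nchar(suf))
  }
  if (anyNA(allele)) {
    bad <- rname[which(is.na(allele))[1]]
    stop("unparseable target name '", bad, "' in ", context,
         ": expected allele suffix ",
         paste(allele_suffix, collapse = " or "))
  }
  gene <- base
  if (!is.null(tx2gene)) {
    idx <- match(base, tx2gene$tx)
    gene <- ifelse(is.na(idx), base, tx2gene$gene[idx])
  }
  list(gene = gene, allele = allele)
}

#' Read and write the equivalence-class table dialect
#'
#' Plain-text interchange for alignment incidence: one line per read,
#' `read_id<TAB>gene:allele[,gene:allele...]`, alleles coded `M`/`P`.
#'
#' @param path File path.
#' @param cell Cell identifier (defaults to file base name).
#' @return `read_ec_table` returns an [alignment_incidence()];
#'   `write_ec_table` returns `path` invisibly.
#' @export
read_ec_table <- function(path, cell = NULL) {
  if (is.null(cell)) cell <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    warning("empty equivalence-class table ", path)
    return(empty_incidence(cell))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("malformed line in ", path, ": '",
         lines[which(lengths(parts) != 2)[1]], "'")
  rid <- vapply(parts, `[`, "", 1L)
  tsets <- strsplit(vapply(parts, `[`, "", 2L), ",", fixed = TRUE)
  hits <- unlist(tsets, use.names = FALSE)
  ga <- strsplit(hits, ":", fixed = TRUE)
  if (any(lengths(ga) != 2))
    stop("unparseable target '", hits[which(lengths(ga) != 2)[1]],
         "' in ", path, " (expected gene:allele)")
  incidence_from_hits(rep(rid, lengths(tsets)),
                      vapply(ga, `[`, "", 1L),
                      vapply(ga, `[`, "", 2L),
                      cell = cell)
}

#' @param inc An [alignment_incidence()] object.
#' @rdname read_ec_table
#' @export
write_ec_table <- function(inc, path) {
  m <- inc$membership
  tlab <- paste(inc$targets$gene, inc$targets$allele, sep = ":")
  mm <- as(m, "TsparseMatrix")
  sets <- split(tlab[mm@j + 1L], mm@i)
  ord <- order(as.integer(names(sets)))
  sets <- sets[ord]
  lines <- paste0(inc$reads[as.integer(names(sets)) + 1L], "\t",
                  vapply(sets, paste, "", collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Classify reads by mapping ambiguity
#'
#' Partitions reads into the four mutually exclusive categories defined by
#' their alignment target sets: a *unique* read maps to one allele of one
#' gene; an *allelic* multi-read maps to both alleles of a single gene; a
#' *genomic* multi-read maps to several genes but one allele of each; a
#' *complex* multi-read maps to several genes with both alleles of at
#' least one.
#'
#' @param inc An [alignment_incidence()] object.
#' @return List with `category` (factor per read, levels `unique`,
#'   `genomic_multi`, `allelic_multi`, `complex_multi`) and `fractions`
#'   (named numeric summing to 1).
#' @export
classify_reads <- function(inc) {
  lev <- c("unique", "genomic_multi", "allelic_multi", "complex_multi")
  m <- inc$membership
  if (nrow(m) == 0) {
    return(list(category = factor(character(), levels = lev),
                fractions = setNames(rep(NaN, 4), lev)))
  }
  gidx <- match(inc$targets$gene, unique(inc$targets$gene))
  gmat <- Matrix::sparseMatrix(i = seq_along(gidx), j = gidx, x = 1,
                               dims = c(ncol(m), max(gidx)))
  per_gene <- m %*% gmat                       # reads x genes, entries 0/1/2
  n_targets <- Matrix::rowSums(m)
  n_genes <- Matrix::rowSums(per_gene > 0)
  has_both <- Matrix::rowSums(per_gene == 2) > 0
  cat <- ifelse(n_targets == 1, "unique",
         ifelse(n_genes == 1, "allelic_multi",
         ifelse(has_both, "complex_multi", "genomic_multi")))
  cat <- factor(cat, levels = lev)
  f <- table(cat) / length(cat)
  list(category = cat,
       fractions = setNames(as.numeric(f), names(f)))
}
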