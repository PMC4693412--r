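# Readers and writers for the pipeline's plain-text formats: genotype TSV
# (individuals x SNPs) plus a map-like locus table, phenotype TSV,
# annotation TSV/BED, and network exports (edge-list TSV, GraphML).

#' Read a genotype matrix from TSV
#'
#' Expects a header row; column 1 is `individual_id`, the remaining columns
#' are SNP dosages coded 0/1/2 with `NA` for missing. Unknown codes are
#' rejected with their coordinates. An optional locus table (`snp`,
#' `chrom`, `pos`, tab-separated) supplies genomic positions.
#'
#' @param path genotype TSV path.
#' @param loci_path optional locus TSV path.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, loci_path = NULL) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "individual_id") {
    stop("genotype file must have 'individual_id' as its first column")
  }
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  bad <- which(!(vals %in% c(0, 1, 2) | is.na(vals)))
  if (length(bad)) {
    i <- (bad[1] - 1) %% nrow(vals) + 1
    j <- (bad[1] - 1) %/% nrow(vals) + 1
    stop(sprintf("parse error in %s: invalid genotype '%s' (individual %s, SNP %s)",
                 path, vals[bad[1]], ids[i], colnames(vals)[j]))
  }
  chrom <- pos <- NULL
  if (!is.null(loci_path)) {
    if (!file.exists(loci_path)) stop("locus file not found: ", loci_path)
    loci <- utils::read.delim(loci_path, stringsAsFactors = FALSE)
    if (!all(c("snp", "chrom", "pos") %in% names(loci))) {
      stop("locus file must have columns snp, chrom, pos")
    }
    miss <- setdiff(colnames(vals), loci$snp)
    if (length(miss)) stop("locus file lacks SNPs: ", paste(utils::head(miss, 5), collapse = ", "))
    loci <- loci[match(colnames(vals), loci$snp), ]
    chrom <- as.character(loci$chrom)
    pos <- as.integer(loci$pos)
  }
  message(sprintf("read_genotypes: %d individuals x %d SNPs from %s",
                  nrow(vals), ncol(vals), path))
  genotype_matrix(vals, snp_ids = colnames(vals), chrom = chrom, pos = pos,
                  individual_ids = ids)
}

#' Write a genotype matrix to TSV
#'
#' @param g a [genotype_matrix()].
#' @param path genotype TSV path.
#' @param loci_path optional locus TSV path (`snp`, `chrom`, `pos`).
#' @return Invisibly, the genotype path.
#' @export
write_genotypes <- function(g, path, loci_path = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  out <- data.frame(individual_id = g$individual_ids, g$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(loci_path)) {
    loci <- data.frame(snp = g$snp_ids, chrom = g$chrom, pos = g$pos)
    utils::write.table(loci, loci_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' Requires columns `individual_id`, `age`, `sex`, and either `bmi` or both
#' `weight` and `height`.
#'
#' @param path phenotype TSV path.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "age", "sex")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("phenotype file lacks columns: ", paste(miss, collapse = ", "))
  message(sprintf("read_phenotypes: %d individuals from %s", nrow(tab), path))
  phenotype_table(
    individual_id = tab$individual_id, age = tab$age, sex = tab$sex,
    weight = if ("weight" %in% names(tab)) tab$weight else NULL,
    height = if ("height" %in% names(tab)) tab$height else NULL,
    bmi = if ("bmi" %in% names(tab)) tab$bmi else NULL
  )
}

#' Write a phenotype table to TSV
#'
#' @param pheno a [phenotype_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(as.data.frame(pheno), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene annotation from TSV or BED
#'
#' TSV format: columns `gene`, `chrom`, `start`, `end` (1-based closed),
#' optional `window_pad`. BED format: `chrom start end name` (0-based
#' half-open), converted to the internal 1-based closed convention.
#'
#' @param path annotation path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @param window_pad pad used when the file carries none.
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path, format = c("tsv", "bed"), window_pad = 5e5) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "bed") {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 4) stop("BED annotation needs 4 columns: chrom start end name")
    ann <- gene_annotation(gene = tab[[4]], chrom = tab[[1]],
                           start = tab[[2]] + 1, end = tab[[3]],
                           window_pad = window_pad)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("gene", "chrom", "start", "end")
    miss <- setdiff(req, names(tab))
    if (length(miss)) stop("annotation file lacks columns: ", paste(miss, collapse = ", "))
    ann <- gene_annotation(gene = tab$gene, chrom = tab$chrom,
                           start = tab$start, end = tab$end,
                           window_pad = if ("window_pad" %in% names(tab)) tab$window_pad else window_pad)
  }
  message(sprintf("read_annotation: %d genes from %s", nrow(ann), path))
  ann
}

#' Write gene annotation
#'
#' @param ann a [gene_annotation()].
#' @param path output path.
#' @param format `"tsv"` (1-based closed) or `"bed"` (0-based half-open).
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(ann, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- data.frame(chrom = ann$chrom, start = ann$start - 1, end = ann$end,
                      name = ann$gene)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Export a network to edge-list TSV or GraphML
#'
#' Edge lists carry `source`, `target`, `weight` (IG). GraphML keeps node
#' attributes (`mi`, and `gene_labels` when a membership matrix is given)
#' and is loadable by standard renderers.
#'
#' @param net a `sen_network`.
#' @param path output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @param membership optional logical SNP-by-gene matrix; labels are joined
#'   with `";"` into a `gene_labels` node attribute.
#' @return Invisibly, `path`.
#' @export
write_graph_file <- function(net, path, format = c("edgelist", "graphml"),
                             membership = NULL) {
  format <- match.arg(format)
  gr <- .as_igraph(net)
  if (!is.null(membership)) {
    labs <- vapply(igraph::V(gr)$name, function(id) {
      if (!id %in% rownames(membership)) return("")
      paste(colnames(membership)[membership[id, ]], collapse = ";")
    }, character(1))
    gr <- igraph::set_vertex_attr(gr, "gene_labels", value = unname(labs))
  }
  if (format == "edgelist") {
    el <- igraph::as_edgelist(gr, names = TRUE)
    w <- igraph::E(gr)$weight
    out <- data.frame(source = el[, 1], target = el[, 2],
                      weight = if (is.null(w)) NA_real_ else w)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(gr, path, format = "graphml")
  }
  invisible(path)
}

#' Import a network written by [write_graph_file()]
#'
#' @param path input path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return An igraph object.
#' @export
read_graph_file <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("graph file not found: ", path)
  if (format == "edgelist") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(tab, directed = FALSE)
  } else {
    igraph::read_graph(path, format = "graphml")
  }
}
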