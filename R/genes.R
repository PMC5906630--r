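#' Gene annotation
#'
#' Per-gene transcription anchors: transcription start site (TSS) and
#' polyadenylation site (polyA), with strand. These anchor all metagene and
#' gene-body computation. For `+` genes `tss < polya`; for `-` genes
#' `tss > polya`. Coordinates are 0-based base positions.
#'
#' @param id Character vector of unique gene identifiers.
#' @param chrom,strand,tss,polya Per-gene chromosome, strand (`+`/`-`), TSS
#'   and polyA coordinates.
#' @param genome A [genome()] for coordinate validation.
#' @return A `GeneAnnotation` (data frame subclass).
#' @export
gene_annotation <- function(id, chrom, strand, tss, polya, genome) {
  stopifnot_genome(genome)
  id <- as.character(id)
  chrom <- as.character(chrom)
  strand <- as.character(strand)
  tss <- as.numeric(tss)
  polya <- as.numeric(polya)
  if (anyDuplicated(id)) stop("gene ids must be unique")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  bad_chrom <- !(chrom %in% genome$chrom_names)
  if (any(bad_chrom))
    stop(sprintf("gene %s: unknown chromosome", id[which(bad_chrom)[1]]))
  if (any(tss == polya)) stop("tss must differ from polya")
  bad_dir <- (strand == "+" & tss >= polya) | (strand == "-" & tss <= polya)
  if (any(bad_dir))
    stop(sprintf("gene %s: tss/polya order contradicts strand",
                 id[which(bad_dir)[1]]))
  lens <- genome$chrom_lengths[chrom]
  oob <- tss < 0 | tss >= lens | polya < 0 | polya >= lens
  if (any(oob))
    stop(sprintf("gene %s: coordinates outside chromosome",
                 id[which(oob)[1]]))
  out <- data.frame(id = id, chrom = chrom, strand = strand,
                    tss = tss, polya = polya, stringsAsFactors = FALSE)
  class(out) <- c("GeneAnnotation", "data.frame")
  out
}

#' Read a gene table (TSV)
#'
#' Expects a header line with columns `id`, `chrom`, `strand`, `tss`,
#' `polya`. Strand consistency of tss/polya is enforced.
#'
#' @param path Path to the TSV file.
#' @param genome A [genome()].
#' @return A [gene_annotation()].
#' @export
read_gene_table <- function(path, genome) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("id", "chrom", "strand", "tss", "polya")
  if (!all(need %in% names(tab)))
    stop(sprintf("gene table must have columns: %s",
                 paste(need, collapse = ", ")))
  gene_annotation(tab$id, tab$chrom, tab$strand, tab$tss, tab$polya, genome)
}

#' Write a gene table (TSV)
#'
#' @param genes A [gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(as.data.frame(genes)[, c("id", "chrom", "strand",
                                              "tss", "polya")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

gene_length <- function(genes) abs(genes$polya - genes$tss)

# +1 for '+' strand, -1 for '-': the direction of transcription.
gene_direction <- function(genes) ifelse(genes$strand == "+", 1, -1)
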