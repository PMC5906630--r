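# Shared in-code fixtures: tiny deterministic genomes and fragment sets.

# genome from explicit sequences
genome_from_seqs <- function(...) {
  seqs <- c(...)
  genome(setNames(nchar(seqs), names(seqs)), seqs)
}

# sequence-free genome of given lengths
bare_genome <- function(lengths) genome(lengths)

# deterministic pseudo-random fragments on a genome
random_fragments <- function(genome, n, len_range = c(50, 300), seed = 1) {
  set.seed(seed)
  cn <- sample(genome$chrom_names, n, replace = TRUE)
  L <- genome$chrom_lengths[cn]
  len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  len <- pmin(len, L)
  start <- floor(runif(n) * (L - len))
  fragment_set(cn, start, start + len, genome, "random")
}

# constant-value coverage track
constant_track <- function(genome, value = 1, normalization = "genome_mean") {
  coverage_track(lapply(setNames(as.list(genome$chrom_lengths),
                                 genome$chrom_names),
                        function(L) rep(value, L)),
                 genome, normalization = normalization)
}

# track from explicit per-chromosome vectors
track_from_values <- function(genome, values, normalization = "raw") {
  coverage_track(values, genome, normalization = normalization)
}
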