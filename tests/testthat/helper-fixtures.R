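# Shared in-code fixtures.

make_dataset <- function(g, pos = NULL, chrom = "1", populations = NULL) {
  g <- as.matrix(g)
  n <- nrow(g); m <- ncol(g)
  if (is.null(pos)) pos <- seq_len(m) * 1e4
  if (is.null(populations)) populations <- rep("pop1", n)
  genotype_dataset(
    g,
    samples = data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                         population = populations,
                         stringsAsFactors = FALSE),
    variants = data.frame(chrom = chrom, id = sprintf("v%04d", seq_len(m)),
                          pos = pos, a1 = "A", a2 = "B",
                          stringsAsFactors = FALSE))
}

# one-chromosome variant table for call_roh_sample
make_variants <- function(pos, chrom = "1") {
  data.frame(chrom = chrom, id = sprintf("v%04d", seq_along(pos)),
             pos = pos, a1 = "A", a2 = "B", stringsAsFactors = FALSE)
}

tiny_config <- function() {
  sim_config(n_chromosomes = 2, chromosome_length_bp = 2e7,
             snp_spacing_bp = 2e4)
}

# segments data.frame shorthand
seg <- function(sample_id, chrom, start, end) {
  data.frame(sample_id = sample_id, chrom = as.character(chrom),
             start_bp = start, end_bp = end, stringsAsFactors = FALSE)
}
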