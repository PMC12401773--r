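chr_sizes <- function(...) {
  s <- c(...)
  data.frame(chrom = names(s), size_bp = unname(s), stringsAsFactors = FALSE)
}

test_that("window counts follow interval arithmetic on half-open windows", {
  sizes <- chr_sizes("1" = 5e5)
  # ROH [150,001, 250,000] 1-based inclusive = [150,000, 250,000) half-open:
  # touches windows [100k,200k) and [200k,300k) only
  tab <- roh_table(seg("a", 1, 150001, 250000),
                   samples = data.frame(sample_id = "a", population = "p"))
  tr <- window_counts(tab, "p", sizes)
  expect_equal(tr$count, c(0, 1, 1, 0, 0))
  expect_equal(attr(tr, "n"), 1)
  # no ROH -> all zero
  tab0 <- roh_table(seg(character(), character(), numeric(), numeric()),
                    samples = data.frame(sample_id = "a", population = "p"))
  expect_true(all(window_counts(tab0, "p", sizes)$count == 0))
})

test_that("summed window counts equal per-individual window touches", {
  set.seed(131)
  sizes <- chr_sizes("1" = 1e7, "2" = 6e6)
  for (rep in 1:25) {
    tab <- simulate_null_roh_table(8, sizes, mean_nroh = 6,
                                   seed = 1000 + rep)
    tr <- window_counts(tab, "null", sizes)
    # brute-force double count: per individual, enumerate touched windows
    brute <- 0
    for (id in unique(tab$sample_id)) {
      s <- tab[tab$sample_id == id, ]
      touched <- character(0)
      for (r in seq_len(nrow(s))) {
        w0 <- floor((s$start_bp[r] - 1) / 1e5)
        w1 <- floor((s$end_bp[r] - 1) / 1e5)
        touched <- union(touched, paste(s$chrom[r], w0:w1))
      }
      brute <- brute + length(touched)
    }
    expect_equal(sum(tr$count), brute)
  }
})

test_that("the Bonferroni level is a plain division", {
  expect_identical(bonferroni_alpha(0.05, 2500), 2e-5)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 28000), 0.05 / 28000)
})

test_that("exact binomial tails match term-wise summation", {
  for (n in c(1, 5, 17, 35)) {
    for (p in c(0.01, 0.05, 0.3)) {
      for (k in 0:n) {
        expect_equal(binom_tail(k, n, p), oracle_binom_tail(k, n, p),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("saturated adjacent windows merge into a single island", {
  sizes <- chr_sizes("1" = 2e6)
  # all 35 individuals share ROH across five adjacent windows
  segs <- do.call(rbind, lapply(1:35, function(i)
    seg(sprintf("i%02d", i), 1, 500001, 1000000)))
  tab <- roh_table(segs, samples = data.frame(
    sample_id = sprintf("i%02d", 1:35), population = "p"))
  tr <- window_counts(tab, "p", sizes)
  isl <- detect_islands(tr, null_p = 0.05,
                        alpha_per_window = bonferroni_alpha(0.05, 2500))
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 5e5)
  expect_equal(isl$end, 1e6)
  expect_equal(isl$length_bp, 5e5)
  expect_equal(isl$length_bp %% attr(tr, "window_bp"), 0)
  # all-zero track -> no islands
  tab0 <- roh_table(seg(character(), character(), numeric(), numeric()),
                    samples = attr(tab, "samples"))
  tr0 <- window_counts(tab0, "p", sizes)
  expect_equal(nrow(detect_islands(tr0, alpha_per_window = 2e-5)), 0)
})

test_that("island sharing is bounded by its maximum and counts any overlap", {
  island <- data.frame(chrom = "1", start = 5e5, end = 1e6)
  segs <- do.call(rbind, lapply(1:10, function(i)
    seg(sprintf("i%02d", i), 1, 600001, 700000)))
  tab <- roh_table(segs, samples = data.frame(
    sample_id = sprintf("i%02d", 1:10), population = "p"))
  expect_equal(island_sharing(island, tab, "p"), 100)
  far <- roh_table(seg("i01", 1, 1.5e6, 1.8e6), samples = attr(tab, "samples"))
  expect_equal(island_sharing(island, far, "p"), 0)
  # mean sharing <= max sharing across random island sets
  set.seed(141)
  sizes <- chr_sizes("1" = 1e7)
  for (rep in 1:20) {
    tb <- simulate_null_roh_table(12, sizes, mean_nroh = 15,
                                  seed = 2000 + rep)
    tr <- window_counts(tb, "null", sizes)
    isl <- detect_islands(tr, alpha_per_window = 0.05)  # permissive on purpose
    if (!nrow(isl)) next
    isl <- attach_island_sharing(isl, tb, "null")
    expect_lte(mean(isl$sharing_pct), max(isl$sharing_pct))
  }
})

test_that("island matching is reciprocal, symmetric and shift-invariant", {
  a <- data.frame(chrom = "1", start = 0, end = 1e6)
  b_same <- data.frame(chrom = "1", start = 0, end = 1e6)
  b_half <- data.frame(chrom = "1", start = 5e5, end = 1.5e6)
  b_nested <- data.frame(chrom = "1", start = 1e5, end = 1e6)
  m1 <- match_islands(a, b_same)
  expect_true(m1$same_island)
  expect_equal(c(m1$frac_a, m1$frac_b), c(1, 1))
  m2 <- match_islands(a, b_half)
  expect_false(m2$same_island)  # 50% of each
  m3 <- match_islands(a, b_nested)
  expect_true(m3$same_island)   # 90% of A, 100% of B
  # symmetry and translation invariance
  m_ab <- match_islands(a, b_nested)
  m_ba <- match_islands(b_nested, a)
  expect_equal(m_ab$same_island, m_ba$same_island)
  expect_equal(m_ab$frac_a, m_ba$frac_b)
  shift <- 7.3e6
  m_sh <- match_islands(transform(a, start = start + shift,
                                  end = end + shift),
                        transform(b_nested, start = start + shift,
                                  end = end + shift))
  expect_equal(m_sh$overlap_bp, m_ab$overlap_bp)
  expect_equal(m_sh$same_island, m_ab$same_island)
})

test_that("island filters apply the stated thresholds inclusively", {
  isl <- data.frame(chrom = "1", start = 0, end = c(1.5e6, 1e6),
                    length_bp = c(1.5e6, 1e6),
                    sharing_pct = c(89.9, 95))
  expect_equal(nrow(filter_islands(isl, "high_representation")), 1)
  expect_equal(filter_islands(isl, "high_representation")$sharing_pct, 95)
  expect_equal(filter_islands(isl, "long")$length_bp, 1.5e6)
  expect_error(filter_islands(isl, "bogus"))
})

test_that("metapopulation pooling reduces to the single-population run", {
  set.seed(151)
  sizes <- chr_sizes("1" = 5e6)
  tb <- simulate_null_roh_table(20, sizes, mean_nroh = 10, seed = 3000)
  grouping <- data.frame(population = "null", group = "G")
  meta <- metapopulation_islands(tb, grouping, sizes,
                                 n_windows_bonferroni = 2500)
  tr <- window_counts(tb, "null", sizes)
  solo <- detect_islands(tr, alpha_per_window = bonferroni_alpha(0.05, 2500))
  expect_equal(nrow(meta$G), nrow(solo))
  if (nrow(solo)) {
    expect_equal(meta$G$start, solo$start)
    expect_equal(meta$G$end, solo$end)
  }
  expect_error(metapopulation_islands(
    tb, data.frame(population = "other", group = "G"), sizes), "absent")
})

test_that("pooling two populations with a shared planted island raises the lower sharing", {
  sizes <- chr_sizes("1" = 5e6)
  mk <- function(pop, n, carriers) {
    segs <- do.call(rbind, lapply(seq_len(carriers), function(i)
      seg(sprintf("%s_%02d", pop, i), 1, 1000001, 1500000)))
    samples <- data.frame(sample_id = sprintf("%s_%02d", pop, seq_len(n)),
                          population = pop)
    roh_table(segs, samples = samples)
  }
  ta <- mk("A", 20, 18)  # 90% sharing
  tb <- mk("B", 10, 5)   # 50% sharing
  pooled <- roh_table(rbind(as.data.frame(ta), as.data.frame(tb)),
                      samples = rbind(attr(ta, "samples"),
                                      attr(tb, "samples")))
  island <- data.frame(chrom = "1", start = 1e6, end = 1.5e6)
  sh_a <- island_sharing(island, pooled, "A")
  sh_b <- island_sharing(island, pooled, "B")
  sh_pool <- island_sharing(island, pooled, c("A", "B"))
  expect_equal(sh_a, 90)
  expect_equal(sh_b, 50)
  expect_equal(sh_pool, 100 * 23 / 30)
  expect_gt(sh_pool, min(sh_a, sh_b))
})

test_that("gene overlap against a GFF3 annotation matches all-pairs brute force", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  set.seed(161)
  starts <- sort(sample(1:4.9e6, 30))
  ends <- starts + sample(2e4:2e5, 30, replace = TRUE)
  lines <- c("##gff-version 3",
             sprintf("1\ttest\tgene\t%d\t%d\t.\t+\t.\tID=gene%02d;Name=G%02d",
                     starts, ends, 1:30, 1:30))
  writeLines(lines, gff)
  islands <- data.frame(chrom = "1",
                        start = c(1e6, 3e6), end = c(1.5e6, 3.2e6))
  res <- gene_overlap(islands, gff)
  for (i in 1:2) {
    # quadratic oracle on 1-based inclusive gene coords vs half-open island
    hit <- which(starts <= islands$end[i] & ends >= islands$start[i] + 1)
    expect_setequal(res[[i]]$gene, sprintf("G%02d", hit))
    expect_false(is.unsorted(res[[i]]$start))
  }
  # gene abutting the half-open island end must not be reported
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\ttest\tgene\t1500001\t1600000\t.\t+\t.\tID=gx;Name=GX"),
             gff2)
  res2 <- gene_overlap(data.frame(chrom = "1", start = 1e6, end = 1.5e6),
                       gff2)
  expect_equal(nrow(res2[[1]]), 0)
  # fully contained gene is reported
  gff3 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\ttest\tgene\t1100000\t1200000\t.\t+\t.\tID=gy;Name=GY"),
             gff3)
  expect_equal(gene_overlap(data.frame(chrom = "1", start = 1e6,
                                       end = 1.5e6), gff3)[[1]]$gene, "GY")
})
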