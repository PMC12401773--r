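test_that("length classes partition [0.3 Mb, Inf) with the stated bounds", {
  expect_equal(as.character(classify_length(400000)), "ROH1")
  expect_equal(as.character(classify_length(500000)), "ROH2")  # upper bin
  expect_equal(as.character(classify_length(8e6)), "ROH5")     # 8 Mb closed
  expect_equal(as.character(classify_length(8000001)), "ROH6") # strictly > 8
  expect_error(classify_length(250000), "0.3 Mb")
  # every length maps to exactly one class
  lens <- seq(3e5, 2e7, by = 1e5)
  expect_false(anyNA(classify_length(lens)))
})

test_that("F_ROH follows the long-ROH sum over the genome denominator", {
  expect_equal(compute_f_roh(data.frame(length_bp = numeric())), 0)
  expect_equal(compute_f_roh(data.frame(length_bp = 3e6)), 0.001)
  expect_equal(compute_f_roh(data.frame(length_bp = c(2e6, 1e6))),
               2e6 / 3e9)  # only the 2 Mb segment passes 1.5 Mb
  # non-increasing in the threshold; threshold 0 recovers total SROH
  segs <- data.frame(length_bp = c(4e5, 1.6e6, 9e6))
  f <- vapply(c(0, 0.5, 1.5, 5, 10),
              function(t) compute_f_roh(segs, threshold_mb = t), numeric(1))
  expect_true(all(diff(f) <= 0))
  expect_equal(f[1] * 3e9, sum(segs$length_bp))
})

test_that("F_IS matches direct formula arithmetic and its boundary cases", {
  # O = E -> 0; N=100, E=50, O=40 -> -0.2 (constructed via equal frequencies)
  g <- rep(c(0L, 1L), 50)
  freqs <- rep(0.5, 100)
  r <- compute_f_is(g, freqs, correct = FALSE)
  expect_equal(r$n, 100)
  expect_equal(r$e_hom, 50)
  expect_equal(r$o_hom, 50)
  expect_equal(r$f_is, 0)
  g2 <- c(rep(0L, 40), rep(1L, 60))
  expect_equal(compute_f_is(g2, freqs, correct = FALSE)$f_is, -0.2)
  # fully homozygous sample -> exactly 1 regardless of frequencies
  set.seed(5)
  sim <- simulate_outbred(tiny_config(), 10, seed = 55)
  ds <- sim$dataset
  ds$genotypes[1, ] <- ifelse(ds$genotypes[1, ] == 1L, 0L, ds$genotypes[1, ])
  ds <- genotype_dataset(ds$genotypes, ds$samples, ds$variants)
  fr <- allele_frequencies(ds)
  ac <- 2 * colSums(!is.na(ds$genotypes))
  expect_equal(compute_f_is(ds$genotypes[1, ], fr, ac)$f_is, 1)
})

test_that("population summaries reproduce hand-checked reference rows", {
  ref <- wm_reference_consistency()
  # transcribed class totals must re-derive every printed mean and share
  expect_lte(ref$max_abs_difference, 0.01 + 1e-8)
  rec <- ref$recomputed
  tot <- rec[rec$category == "TOTAL", ]
  expect_equal(tot$nroh_per_ind[tot$population == "SPEA"], 21757 / 35)
  expect_equal(round(tot$nroh_per_ind[tot$population == "SPEA"], 2), 621.63)
  roh6 <- rec[rec$category == "ROH6", ]
  expect_equal(round(roh6$sroh_per_ind[roh6$population == "MAAS"], 2), 43.05)
})

test_that("summarize_population aggregates called segments per class", {
  tab <- roh_table(
    rbind(seg("a", 1, 1e6, 1.4e6 - 1),   # 0.4 Mb  ROH1
          seg("a", 1, 5e6, 7.5e6 - 1),   # 2.5 Mb  ROH4
          seg("b", 2, 1e6, 10e6 - 1)),   # 9 Mb    ROH6
    samples = data.frame(sample_id = c("a", "b"),
                         population = "p1", stringsAsFactors = FALSE))
  s <- summarize_population(tab, "p1")
  expect_equal(s$nroh[s$category == "ROH1"], 1)
  expect_equal(s$carriers[s$category == "ROH6"], 1)
  expect_equal(s$carriers_pct[s$category == "ROH6"], 50)
  expect_equal(s$nroh[s$category == "TOTAL"], 3)
  expect_equal(s$sroh_mb[s$category == "TOTAL"], 11.9)
  expect_equal(s$sroh_per_ind[s$category == "TOTAL"], 5.95)
  # single individual with one 0.4 Mb segment: all totals equal it
  tab1 <- roh_table(seg("a", 1, 1e6, 1.4e6 - 1),
                    samples = data.frame(sample_id = "a", population = "q"))
  s1 <- summarize_population(tab1, "q")
  expect_equal(s1$nroh[s1$category == "TOTAL"], 1)
  expect_equal(s1$sroh_mb[s1$category == "TOTAL"], 0.4)
  expect_error(summarize_population(tab1, "nope"), "unknown population")
})

test_that("class counts and lengths are conserved across the partition", {
  set.seed(31)
  co <- simulate_cohort(tiny_config(), "first_cousin", 12, seed = 32)
  tab <- call_roh(co$dataset)
  recs <- inbreeding_records(tab, genome_bp = 4e7)
  nroh_cols <- paste0("nroh_ROH", 1:6)
  sroh_cols <- paste0("sroh_ROH", 1:6)
  expect_equal(rowSums(recs[, nroh_cols]), as.numeric(recs$nroh))
  expect_equal(rowSums(recs[, sroh_cols]), recs$sroh_mb, tolerance = 1e-9)
})

test_that("chromosome coverage averages per-individual percentages", {
  sizes <- data.frame(chrom = c("1", "2"), size_bp = c(1e8, 5e7))
  tab <- roh_table(
    rbind(seg("a", 1, 1, 1e7),          # 10% of chr1
          seg("b", 1, 1, 4e6),          # 4%
          seg("b", 1, 2e7, 2e7 + 6e6 - 1)),  # +6% -> 10%
    samples = data.frame(sample_id = c("a", "b"), population = "p"))
  cd <- chromosome_distribution(tab, sizes, min_length_mb = 0.3)
  expect_equal(cd$coverage_pct[cd$chrom == "1"], 10)
  expect_equal(cd$nroh[cd$chrom == "1"], 3)
  expect_equal(cd$coverage_pct[cd$chrom == "2"], 0)
  # single 10 Mb ROH on a 100 Mb chromosome, one individual -> 10%
  tab1 <- roh_table(seg("a", 1, 1, 1e7),
                    samples = data.frame(sample_id = "a", population = "p"))
  expect_equal(chromosome_distribution(tab1, sizes)$coverage_pct[1], 10)
  # chromosome missing from the size table
  tab_bad <- roh_table(seg("a", "7", 1, 1e6),
                       samples = data.frame(sample_id = "a",
                                            population = "p"))
  expect_error(chromosome_distribution(tab_bad, sizes), "absent")
})

test_that("correlation structure links the longest class to F_ROH", {
  # self-correlation and exact negation
  set.seed(61)
  x <- rnorm(30)
  expect_equal(suppressWarnings(cor(x, x, method = "spearman")), 1)
  # cohort mixing consanguineous, drifted and outbred individuals; 10-kb SNP
  # spacing so that 0.3-0.5 Mb segments clear the 30-SNP floor and the short
  # classes are populated (at 20-kb spacing ROH1 is structurally uncallable)
  cfg <- sim_config(n_chromosomes = 2, chromosome_length_bp = 3e7,
                    snp_spacing_bp = 1e4)
  co <- simulate_cohort(cfg, "first_cousin", 12, seed = 62)
  ou <- simulate_outbred(cfg, 12, seed = 63)
  dr <- simulate_drift(cfg, ne = 25, generations = 40, seed = 64,
                       n_sample = 12)
  g <- rbind(co$dataset$genotypes, ou$dataset$genotypes,
             dr$dataset$genotypes)
  samp <- rbind(co$dataset$samples, ou$dataset$samples, dr$dataset$samples)
  ds <- genotype_dataset(g, samp, co$dataset$variants)
  tab <- call_roh(ds)
  recs <- inbreeding_records(tab, genome_bp = 6e7)
  ch <- correlation_heatmap_inputs(recs)
  expect_equal(dim(ch$rho), c(13, 13))
  expect_equal(unname(diag(ch$rho)), rep(1, 13))
  expect_gt(ch$rho["sroh_ROH6", "f_roh"], ch$rho["sroh_ROH1", "f_roh"])
  expect_equal(sort(ch$order), sort(rownames(ch$rho)))
})

test_that("mixed-model weights identify the class that drives F_ROH", {
  set.seed(71)
  n <- 60
  recs <- data.frame(population = rep(c("p1", "p2", "p3"), each = n / 3))
  for (k in 1:6) recs[[paste0("sroh_ROH", k)]] <- rnorm(n)
  # F_ROH an exact scaled copy of the ROH6 column
  recs$f_roh <- 0.01 * recs$sroh_ROH6
  w <- suppressWarnings(lmm_category_weights(recs))
  expect_equal(w$coefficient[w$category == "ROH6"], 1, tolerance = 1e-6)
  expect_true(all(abs(w$coefficient[w$category != "ROH6"]) < 1e-6))
  # permuted response: no coefficient should look strong
  recs$f_roh <- sample(recs$f_roh)
  w2 <- suppressWarnings(lmm_category_weights(recs))
  expect_true(all(abs(w2$coefficient) < 0.5))
})

test_that("simulated consanguineous cohorts weight ROH6 heaviest", {
  co <- simulate_cohort(sim_config(), "first_cousin", 15, seed = 81)
  co2 <- simulate_cohort(sim_config(), "second_cousin", 15, seed = 82)
  dr <- simulate_drift(sim_config(), ne = 25, generations = 40, seed = 83,
                       n_sample = 15)
  g <- rbind(co$dataset$genotypes, co2$dataset$genotypes,
             dr$dataset$genotypes)
  samp <- rbind(co$dataset$samples, co2$dataset$samples, dr$dataset$samples)
  ds <- genotype_dataset(g, samp, co$dataset$variants)
  recs <- inbreeding_records(call_roh(ds), genome_bp = 2e8)
  w <- suppressWarnings(lmm_category_weights(recs))
  expect_equal(w$category[which.max(abs(w$coefficient))], "ROH6")
})
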