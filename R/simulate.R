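# Synthetic genotype generator. Haplotypes are carried as founder-segment
# lists (per chromosome: segment end positions plus the founder-haplotype id
# of each segment), so autozygosity ground truth is defined at
# founder-haplotype resolution: a truth tract is a region where the maternal
# and paternal copies descend from the same founder haplotype. Alleles are
# spliced from founder allele matrices only when genotypes are emitted.

#' Simulation configuration
#'
#' Defaults describe a desk-scale genotyping panel: 4 chromosomes of 50 Mb
#' with one SNP every 20 kb (10,000 variants), allele frequencies drawn
#' uniformly on [0.05, 0.5], and a uniform recombination rate of 1 cM/Mb
#' (0.5 Morgans per chromosome). Large enough to resolve multi-Mb autozygous
#' tracts, small enough for minutes-scale validation runs.
#'
#' @param n_chromosomes number of autosomes.
#' @param chromosome_length_bp length of each chromosome in bp.
#' @param snp_spacing_bp inter-SNP spacing in bp (evenly spaced markers).
#' @param maf_range range of the uniform minor-allele-frequency distribution.
#' @param recomb_rate_cm_per_mb recombination rate, cM/Mb.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_chromosomes = 4, chromosome_length_bp = 5e7,
                       snp_spacing_bp = 2e4, maf_range = c(0.05, 0.5),
                       recomb_rate_cm_per_mb = 1) {
  stopifnot(n_chromosomes >= 1, chromosome_length_bp > 0,
            snp_spacing_bp > 0, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            recomb_rate_cm_per_mb >= 0)
  structure(list(
    n_chromosomes = n_chromosomes,
    chromosome_length_bp = chromosome_length_bp,
    snp_spacing_bp = snp_spacing_bp,
    maf_range = maf_range,
    recomb_rate_cm_per_mb = recomb_rate_cm_per_mb), class = "sim_config")
}

.variant_map <- function(config) {
  pos1 <- seq(config$snp_spacing_bp, config$chromosome_length_bp,
              by = config$snp_spacing_bp)
  do.call(rbind, lapply(seq_len(config$n_chromosomes), function(ch)
    data.frame(chrom = as.character(ch),
               id = sprintf("snp_%d_%d", ch, seq_along(pos1)),
               pos = as.integer(pos1), a1 = "A", a2 = "B",
               stringsAsFactors = FALSE)))
}

#' Simulate founder haplotypes
#'
#' Draws per-variant allele frequencies from the configured MAF distribution
#' and then \code{n_haplotypes} independent haplotypes from them. Evenly
#' spaced variant positions. Deterministic given \code{seed}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_haplotypes number of founder haplotypes (2 per founder).
#' @param seed RNG seed (mandatory).
#' @return List with \code{haplotypes} (n_haplotypes x n_variants 0/1
#'   matrix of allele-1 indicators), \code{variants} (map data.frame) and
#'   \code{freqs} (allele-1 frequencies the alleles were drawn from).
#' @export
simulate_founders <- function(config, n_haplotypes, seed) {
  stopifnot(inherits(config, "sim_config"), n_haplotypes >= 1)
  set.seed(seed)
  variants <- .variant_map(config)
  m <- nrow(variants)
  freqs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  haps <- matrix(stats::rbinom(n_haplotypes * m, 1L,
                               rep(freqs, each = n_haplotypes)),
                 nrow = n_haplotypes)
  list(haplotypes = haps, variants = variants, freqs = freqs)
}

# --- founder-segment haplotype representation -------------------------------
# One chromosome of one haplotype: list(ends = numeric (sorted, last = L),
# fid = integer founder-haplotype ids). Segment i covers
# (ends[i-1], ends[i]].

.founder_hap <- function(fid, config) {
  lapply(seq_len(config$n_chromosomes), function(ch)
    list(ends = config$chromosome_length_bp, fid = fid))
}

# crossover positions -> gamete from two parental chromosome structures
.recombine_chrom <- function(hapA, hapB, L, morgans) {
  k <- stats::rpois(1, morgans)
  from_a <- stats::runif(1) < 0.5
  if (k == 0) return(if (from_a) hapA else hapB)
  cuts <- sort(stats::runif(k, 0, L))
  bounds <- c(0, cuts, L)
  ends <- numeric(0); fid <- integer(0)
  for (i in seq_len(length(bounds) - 1)) {
    src <- if (from_a) hapA else hapB
    a <- bounds[i]; b <- bounds[i + 1]
    if (b > a) {
      seg_starts <- c(0, src$ends[-length(src$ends)])
      sel <- which(src$ends > a & seg_starts < b)
      ends <- c(ends, pmin(src$ends[sel], b))
      fid <- c(fid, src$fid[sel])
    }
    from_a <- !from_a
  }
  # merge adjacent segments with equal founder id
  if (length(fid) > 1) {
    same <- c(fid[-1] == fid[-length(fid)], FALSE)
    ends <- ends[!same]
    fid <- fid[!same]
  }
  list(ends = ends, fid = fid)
}

.meiosis <- function(parent_haps, config) {
  morgans <- config$chromosome_length_bp / 1e6 *
    config$recomb_rate_cm_per_mb / 100
  lapply(seq_len(config$n_chromosomes), function(ch)
    .recombine_chrom(parent_haps[[1]][[ch]], parent_haps[[2]][[ch]],
                     config$chromosome_length_bp, morgans))
}

# intersect two chromosome structures: intervals where founder ids coincide
.autozygous_intervals <- function(h1, h2) {
  bounds <- sort(unique(c(0, h1$ends, h2$ends)))
  starts <- bounds[-length(bounds)]
  stops <- bounds[-1]
  mid <- (starts + stops) / 2
  f1 <- h1$fid[findInterval(mid, c(0, h1$ends), left.open = TRUE)]
  f2 <- h2$fid[findInterval(mid, c(0, h2$ends), left.open = TRUE)]
  eq <- f1 == f2
  if (!any(eq)) return(NULL)
  runs <- rle(eq)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1
  keep <- runs$values
  data.frame(start = starts[idx_start[keep]], end = stops[idx_end[keep]],
             fid = f1[idx_start[keep]])
}

# alleles of one chromosome structure at the variant positions of chromosome ch
.splice_alleles <- function(hap, pos, founder_haps, var_offset) {
  seg <- findInterval(pos, c(0, hap$ends), left.open = TRUE)
  seg[seg > length(hap$fid)] <- length(hap$fid)
  fid <- hap$fid[seg]
  founder_haps[cbind(fid, var_offset + seq_along(pos))]
}

#' Gene-dropping pedigree simulation
#'
#' Transmits founder haplotypes down a pedigree with recombination (crossover
#' count per chromosome ~ Poisson(map length in Morgans), positions uniform,
#' no interference) and returns genotypes for every pedigree member plus the
#' exhaustive ground-truth autozygous tracts of each member: regions where
#' the maternal and paternal copies descend from the same founder haplotype.
#'
#' @param pedigree data.frame with \code{id}, \code{father}, \code{mother}
#'   (NA for founders). Must be acyclic with parents defined before use.
#' @param founders result of \code{\link{simulate_founders}} with at least
#'   2 x (number of pedigree founders) haplotypes.
#' @param config the \code{\link{sim_config}} used for the founders.
#' @param seed RNG seed (mandatory).
#' @param population population label for the emitted samples.
#' @return List with \code{dataset} (a \code{\link{genotype_dataset}} over
#'   all pedigree members) and \code{truth} (data.frame of tracts:
#'   \code{sample_id}, \code{chrom}, \code{start_bp}, \code{end_bp} 1-based
#'   inclusive, \code{founder_hap}).
#' @export
gene_drop <- function(pedigree, founders, config, seed,
                      population = "ped") {
  stopifnot(all(c("id", "father", "mother") %in% names(pedigree)))
  set.seed(seed)
  ids <- pedigree$id
  if (anyDuplicated(ids)) stop("duplicate pedigree ids", call. = FALSE)
  is_founder <- is.na(pedigree$father) & is.na(pedigree$mother)
  if (any(is.na(pedigree$father) != is.na(pedigree$mother)))
    stop("members must have either two parents or none", call. = FALSE)
  n_founders <- sum(is_founder)
  if (nrow(founders$haplotypes) < 2 * n_founders)
    stop("founder pool too small: need ", 2 * n_founders, " haplotypes",
         call. = FALSE)

  # topological order check (parents before children)
  seen <- character(0)
  for (i in seq_len(nrow(pedigree))) {
    if (!is_founder[i] &&
        !all(c(pedigree$father[i], pedigree$mother[i]) %in% seen))
      stop("pedigree is not in parents-first order (or is cyclic)",
           call. = FALSE)
    seen <- c(seen, ids[i])
  }

  haps <- vector("list", nrow(pedigree))
  names(haps) <- ids
  fctr <- 0L
  for (i in seq_len(nrow(pedigree))) {
    if (is_founder[i]) {
      haps[[i]] <- list(.founder_hap(fctr + 1L, config),
                        .founder_hap(fctr + 2L, config))
      fctr <- fctr + 2L
    } else {
      haps[[i]] <- list(.meiosis(haps[[pedigree$father[i]]], config),
                        .meiosis(haps[[pedigree$mother[i]]], config))
    }
  }

  variants <- founders$variants
  m <- nrow(variants)
  g <- matrix(NA_integer_, nrow(pedigree), m)
  truth <- list()
  var_by_chrom <- split(seq_len(m), variants$chrom)
  for (i in seq_len(nrow(pedigree))) {
    for (ch in seq_len(config$n_chromosomes)) {
      vidx <- var_by_chrom[[as.character(ch)]]
      pos <- variants$pos[vidx]
      h1 <- haps[[i]][[1]][[ch]]
      h2 <- haps[[i]][[2]][[ch]]
      a1 <- .splice_alleles(h1, pos, founders$haplotypes, vidx[1] - 1L)
      a2 <- .splice_alleles(h2, pos, founders$haplotypes, vidx[1] - 1L)
      # dosage counts copies of allele 1 ("A"), i.e. allele indicator == 1
      g[i, vidx] <- a1 + a2
      tr <- .autozygous_intervals(h1, h2)
      if (!is.null(tr))
        truth[[length(truth) + 1]] <- data.frame(
          sample_id = ids[i], chrom = as.character(ch),
          start_bp = floor(tr$start) + 1, end_bp = floor(tr$end),
          founder_hap = tr$fid, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample_id = character(), chrom = character(),
               start_bp = numeric(), end_bp = numeric(),
               founder_hap = integer(), stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = ids, population = population,
                        stringsAsFactors = FALSE)
  list(dataset = genotype_dataset(g, samples, variants), truth = truth)
}

#' Pedigree templates for standard mating designs
#'
#' Builds a parents-first pedigree for one family of the requested design,
#' whose final member is the focal offspring: \code{"outbred"} (two founder
#' parents, expected F = 0), \code{"selfing"} (one generation of selfing,
#' F = 1/2), \code{"first_cousin"} (F = 1/16), \code{"second_cousin"}
#' (F = 1/64).
#'
#' @param mating design name.
#' @param prefix id prefix, so family pedigrees can be concatenated.
#' @return data.frame with \code{id}, \code{father}, \code{mother}; the last
#'   row is the focal offspring.
#' @export
family_pedigree <- function(mating = c("outbred", "selfing", "first_cousin",
                                       "second_cousin"),
                            prefix = "f1") {
  mating <- match.arg(mating)
  p <- function(x) paste0(prefix, "_", x)
  ped <- switch(mating,
    outbred = data.frame(
      id = p(c("a", "b", "child")),
      father = c(NA, NA, p("a")),
      mother = c(NA, NA, p("b"))),
    selfing = data.frame(
      id = p(c("a", "b", "s", "child")),
      father = c(NA, NA, p("a"), p("s")),
      mother = c(NA, NA, p("b"), p("s"))),
    first_cousin = data.frame(
      id = p(c("g1", "g2", "sp1", "sp2", "p1", "p2", "c1", "c2", "child")),
      father = c(NA, NA, NA, NA, p("g1"), p("g1"), p("p1"), p("p2"), p("c1")),
      mother = c(NA, NA, NA, NA, p("g2"), p("g2"), p("sp1"), p("sp2"),
                 p("c2"))),
    second_cousin = data.frame(
      id = p(c("g1", "g2", "sp1", "sp2", "sp3", "sp4",
               "p1", "p2", "c1", "c2", "d1", "d2", "child")),
      father = c(NA, NA, NA, NA, NA, NA,
                 p("g1"), p("g1"), p("p1"), p("p2"), p("c1"), p("c2"),
                 p("d1")),
      mother = c(NA, NA, NA, NA, NA, NA,
                 p("g2"), p("g2"), p("sp1"), p("sp2"), p("sp3"), p("sp4"),
                 p("d2"))))
  ped$id <- as.character(ped$id)
  ped$father <- as.character(ped$father)
  ped$mother <- as.character(ped$mother)
  ped
}

#' Simulate a cohort of offspring from a fixed mating design
#'
#' Generates \code{n_offspring} independent families of the requested design
#' (fresh founders per family) and returns the focal offspring only,
#' genotypes plus their ground-truth autozygous tracts.
#'
#' @param config a \code{\link{sim_config}}.
#' @param mating design name (see \code{\link{family_pedigree}}).
#' @param n_offspring number of independent offspring.
#' @param seed RNG seed (mandatory).
#' @param population population label.
#' @return List with \code{dataset}, \code{truth} (as in
#'   \code{\link{gene_drop}}, offspring only) and \code{freqs} (founder
#'   allele-1 frequencies).
#' @export
simulate_cohort <- function(config, mating, n_offspring, seed,
                            population = mating) {
  stopifnot(n_offspring >= 1)
  set.seed(seed)
  variants <- .variant_map(config)
  m <- nrow(variants)
  freqs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  ped1 <- family_pedigree(mating, prefix = "x")
  n_fnd <- sum(is.na(ped1$father))
  g <- matrix(NA_integer_, n_offspring, m)
  truth <- list()
  seeds <- sample.int(2^31 - 2, 2 * n_offspring)
  for (k in seq_len(n_offspring)) {
    fnd <- list(haplotypes = matrix(
      stats::rbinom(2 * n_fnd * m, 1L, rep(freqs, each = 2 * n_fnd)),
      nrow = 2 * n_fnd), variants = variants, freqs = freqs)
    res <- gene_drop(family_pedigree(mating, prefix = paste0("fam", k)),
                     fnd, config, seed = seeds[k], population = population)
    focal <- utils::tail(res$dataset$samples$sample_id, 1)
    g[k, ] <- res$dataset$genotypes[nrow(res$dataset$genotypes), ]
    tr <- res$truth[res$truth$sample_id == focal, , drop = FALSE]
    if (nrow(tr)) {
      tr$sample_id <- sprintf("%s_%03d", population, k)
      truth[[length(truth) + 1]] <- tr
    }
  }
  samples <- data.frame(
    sample_id = sprintf("%s_%03d", population, seq_len(n_offspring)),
    population = population, stringsAsFactors = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample_id = character(), chrom = character(),
               start_bp = numeric(), end_bp = numeric(),
               founder_hap = integer(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(dataset = genotype_dataset(g, samples, variants), truth = truth,
       freqs = freqs)
}

#' Simulate an outbred panmictic sample
#'
#' Independent individuals in Hardy-Weinberg proportions at frequencies drawn
#' from the configured MAF distribution.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n number of individuals.
#' @param seed RNG seed (mandatory).
#' @param population population label.
#' @return List with \code{dataset} and \code{freqs}.
#' @export
simulate_outbred <- function(config, n, seed, population = "outbred") {
  set.seed(seed)
  variants <- .variant_map(config)
  m <- nrow(variants)
  freqs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  g <- matrix(stats::rbinom(n * m, 2L, rep(freqs, each = n)), nrow = n)
  samples <- data.frame(
    sample_id = sprintf("%s_%03d", population, seq_len(n)),
    population = population, stringsAsFactors = FALSE)
  list(dataset = genotype_dataset(g, samples, variants), freqs = freqs)
}

#' Wright-Fisher drift simulation
#'
#' Discrete generations of a random-mating diploid population of constant
#' size \code{ne} with recombination; the final generation is returned.
#' Generation 0 individuals are founder pairs of haplotypes drawn from the
#' configured MAF distribution; \code{generations = 0} returns them
#' unchanged.
#'
#' @param config a \code{\link{sim_config}}.
#' @param ne diploid population size (>= 2).
#' @param generations number of generations to evolve.
#' @param seed RNG seed (mandatory).
#' @param n_sample individuals returned (default all \code{ne}).
#' @param population population label.
#' @return List with \code{dataset} and \code{freqs} (founder frequencies).
#' @export
simulate_drift <- function(config, ne, generations, seed,
                           n_sample = ne, population = "drift") {
  stopifnot(ne >= 2, generations >= 0, n_sample <= ne)
  set.seed(seed)
  variants <- .variant_map(config)
  m <- nrow(variants)
  freqs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  # allele matrices, 2*ne haplotypes; rows 2i-1, 2i belong to individual i
  haps <- matrix(stats::rbinom(2 * ne * m, 1L, rep(freqs, each = 2 * ne)),
                 nrow = 2 * ne)
  pos_by_chrom <- split(variants$pos, variants$chrom)
  idx_by_chrom <- split(seq_len(m), variants$chrom)
  morgans <- config$chromosome_length_bp / 1e6 *
    config$recomb_rate_cm_per_mb / 100
  gamete <- function(h1, h2) {
    out <- integer(m)
    for (ch in as.character(seq_len(config$n_chromosomes))) {
      pos <- pos_by_chrom[[ch]]
      vidx <- idx_by_chrom[[ch]]
      k <- stats::rpois(1, morgans)
      use1 <- stats::runif(1) < 0.5
      if (k == 0) {
        out[vidx] <- if (use1) h1[vidx] else h2[vidx]
      } else {
        cuts <- sort(stats::runif(k, 0, config$chromosome_length_bp))
        phase <- (findInterval(pos, cuts) + !use1) %% 2 == 0
        out[vidx] <- ifelse(phase, h1[vidx], h2[vidx])
      }
    }
    out
  }
  if (generations > 0) {
    for (gen in seq_len(generations)) {
      nxt <- matrix(0L, 2 * ne, m)
      fathers <- sample.int(ne, ne, replace = TRUE)
      mothers <- sample.int(ne, ne, replace = TRUE)
      for (i in seq_len(ne)) {
        nxt[2 * i - 1, ] <- gamete(haps[2 * fathers[i] - 1, ],
                                   haps[2 * fathers[i], ])
        nxt[2 * i, ] <- gamete(haps[2 * mothers[i] - 1, ],
                               haps[2 * mothers[i], ])
      }
      haps <- nxt
    }
  }
  keep <- seq_len(n_sample)
  g <- haps[2 * keep - 1, , drop = FALSE] + haps[2 * keep, , drop = FALSE]
  samples <- data.frame(
    sample_id = sprintf("%s_%03d", population, keep),
    population = population, stringsAsFactors = FALSE)
  list(dataset = genotype_dataset(g, samples, variants), freqs = freqs)
}

#' Plant a shared homozygous region (an island) into a dataset
#'
#' In a random \code{carrier_fraction} of the individuals, both haplotypes
#' over the region are replaced by one fixed haplotype drawn from the
#' per-variant allele frequencies, forcing homozygosity across the region;
#' the other individuals are untouched.
#'
#' @param dataset a \code{\link{genotype_dataset}}.
#' @param chrom,start_bp,end_bp region (1-based inclusive bp); must lie on
#'   the chromosome.
#' @param carrier_fraction fraction of individuals made homozygous
#'   (0 < f <= 1).
#' @param seed RNG seed (mandatory).
#' @param freqs allele-1 frequencies used to draw the planted haplotype;
#'   defaults to the dataset's observed frequencies.
#' @return List with \code{dataset} (modified) and \code{carriers} (sample
#'   ids).
#' @export
plant_island <- function(dataset, chrom, start_bp, end_bp, carrier_fraction,
                         seed, freqs = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            carrier_fraction > 0, carrier_fraction <= 1,
            start_bp >= 1, end_bp > start_bp)
  v <- dataset$variants
  on_chrom <- v$chrom == chrom
  if (!any(on_chrom))
    stop("chromosome ", chrom, " not in dataset", call. = FALSE)
  if (start_bp > max(v$pos[on_chrom]))
    stop("region lies beyond chromosome ", chrom, call. = FALSE)
  set.seed(seed)
  sel <- which(on_chrom & v$pos >= start_bp & v$pos <= end_bp)
  if (is.null(freqs)) freqs <- allele_frequencies(dataset)
  template <- stats::rbinom(length(sel), 1L, freqs[sel])
  n <- nrow(dataset$genotypes)
  carriers <- sort(sample.int(n, max(1, round(carrier_fraction * n))))
  g <- dataset$genotypes
  g[carriers, sel] <- rep(2L * template, each = length(carriers))
  list(dataset = genotype_dataset(g, dataset$samples, dataset$variants),
       carriers = dataset$samples$sample_id[carriers])
}

#' Inject missing genotypes
#'
#' @param dataset a \code{\link{genotype_dataset}}.
#' @param rate per-call missingness probability.
#' @param seed RNG seed.
#' @return Modified \code{genotype_dataset}.
#' @export
add_missingness <- function(dataset, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  set.seed(seed)
  g <- dataset$genotypes
  g[stats::runif(length(g)) < rate] <- NA_integer_
  genotype_dataset(g, dataset$samples, dataset$variants)
}

#' Inject genotyping errors
#'
#' Each affected call is replaced by one of the other two genotype states,
#' chosen uniformly.
#'
#' @param dataset a \code{\link{genotype_dataset}}.
#' @param rate per-call error probability.
#' @param seed RNG seed.
#' @return Modified \code{genotype_dataset}.
#' @export
add_genotype_errors <- function(dataset, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  set.seed(seed)
  g <- dataset$genotypes
  hit <- which(!is.na(g) & stats::runif(length(g)) < rate)
  if (length(hit)) {
    shift <- sample(1:2, length(hit), replace = TRUE)
    g[hit] <- (g[hit] + shift) %% 3L
  }
  genotype_dataset(g, dataset$samples, dataset$variants)
}

#' Simulate a random ROH table under a spatially uniform null
#'
#' Places, for each of \code{n} individuals, a Poisson number of ROH
#' segments uniformly on the genome with lengths drawn uniformly from
#' \code{length_range_bp}. No region is enriched, so the resulting
#' window-count track is the null reference for calibrating island
#' detection.
#'
#' @param n individuals.
#' @param chrom_sizes data.frame with \code{chrom}, \code{size_bp}.
#' @param mean_nroh mean segments per individual.
#' @param length_range_bp segment length range in bp.
#' @param seed RNG seed (mandatory).
#' @param population population label.
#' @return An \code{roh_table}.
#' @export
simulate_null_roh_table <- function(n, chrom_sizes, mean_nroh = 20,
                                    length_range_bp = c(3e5, 5e5), seed,
                                    population = "null") {
  set.seed(seed)
  tot <- sum(chrom_sizes$size_bp)
  segs <- list()
  for (i in seq_len(n)) {
    k <- stats::rpois(1, mean_nroh)
    if (k == 0) next
    len <- stats::runif(k, length_range_bp[1], length_range_bp[2])
    chn <- sample(seq_len(nrow(chrom_sizes)), k, replace = TRUE,
                  prob = chrom_sizes$size_bp)
    start <- floor(stats::runif(k) *
                     pmax(1, chrom_sizes$size_bp[chn] - len)) + 1
    segs[[length(segs) + 1]] <- data.frame(
      sample_id = sprintf("%s_%03d", population, i),
      chrom = chrom_sizes$chrom[chn],
      start_bp = start, end_bp = floor(start + len - 1),
      stringsAsFactors = FALSE)
  }
  seg_df <- if (length(segs)) do.call(rbind, segs) else
    data.frame(sample_id = character(), chrom = character(),
               start_bp = numeric(), end_bp = numeric())
  roh_table(seg_df, samples = data.frame(
    sample_id = sprintf("%s_%03d", population, seq_len(n)),
    population = population, stringsAsFactors = FALSE))
}

#' Ground-truth autozygous genome fraction per sample
#'
#' @param truth truth-tract data.frame (from \code{\link{gene_drop}} or
#'   \code{\link{simulate_cohort}}).
#' @param sample_ids samples to score (zero-tract samples score 0).
#' @param genome_bp total genome length.
#' @return Named numeric vector of autozygous fractions.
#' @export
truth_fraction <- function(truth, sample_ids, genome_bp) {
  out <- stats::setNames(numeric(length(sample_ids)), sample_ids)
  if (nrow(truth)) {
    agg <- tapply(truth$end_bp - truth$start_bp + 1, truth$sample_id, sum)
    out[names(agg)] <- agg / genome_bp
  }
  out
}

#' Write simulated outputs to disk
#'
#' PLINK bed/bim/fam trio, a population TSV and the truth tracts as BED
#' (0-based half-open). Deterministic given its inputs.
#'
#' @param dataset a \code{\link{genotype_dataset}}.
#' @param truth truth-tract data.frame (may have zero rows).
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_sim_outputs <- function(dataset, truth, prefix) {
  write_plink(dataset, prefix)
  utils::write.table(dataset$samples, paste0(prefix, "_pops.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  bed <- data.frame(truth$chrom, truth$start_bp - 1, truth$end_bp,
                    truth$sample_id)
  utils::write.table(bed, paste0(prefix, "_truth.bed"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
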