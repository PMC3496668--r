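test_that("third positions of 4-fold codon families are flagged, others not", {
  # gene ATG | GCT | GGC | CTA | TAA: Ala and Gly third positions are
  # 4-fold; ATG's is not; Leu CTA is 4-fold at the third position
  reg <- toy_gene_region()
  cls <- classify_sites(reg$aln, reg$cds)
  off <- nchar("ACGTAC")
  expect_false(cls$fourfold[off + 3L])            # ATG
  expect_true(cls$fourfold[off + 6L])             # GCT (Ala)
  expect_true(cls$fourfold[off + 9L])             # GGC (Gly)
  expect_true(cls$fourfold[off + 12L])            # CTA (Leu, CTN quartet)
  expect_false(any(cls$fourfold[seq_len(off)]))   # flanks are non-coding
  expect_equal(cls$codon[off + 6L], "GCT")
  # GCT is unpreferred (major Ala codon is GCC), GGC is the preferred Gly
  expect_true(cls$unpreferred[off + 6L])
  expect_false(cls$unpreferred[off + 9L])
})

test_that("minus-strand classification equals that of the reverse complement", {
  plus <- toy_gene_region(strand = "+")
  minus <- toy_gene_region(strand = "-")
  cp <- classify_sites(plus$aln, plus$cds)
  cm <- classify_sites(minus$aln, minus$cds)
  L <- nchar(plus$aln[1L])
  expect_equal(cm$fourfold, rev(cp$fourfold))
  expect_equal(cm$unpreferred, rev(cp$unpreferred))
})

test_that("genes with internal stops and overlapping frames are excluded", {
  reg <- toy_gene_region(codons = c("ATG", "TAA", "GCT", "TAA"))
  cls <- classify_sites(reg$aln, reg$cds)
  expect_equal(attr(cls, "excluded_genes"), "g1")
  expect_false(any(cls$fourfold))
  # overlapping CDS: a 4-fold site under two frames is never eligible
  reg2 <- toy_gene_region()
  cds2 <- rbind(reg2$cds,
                data.frame(start = reg2$cds$start + 1L, end = reg2$cds$end + 1L,
                           strand = "+", frame = 0L, gene = "g2"))
  cls2 <- classify_sites(reg2$aln, cds2)
  expect_true(all(cls2$multi_frame[(reg2$cds$start + 1L):reg2$cds$end]))
  expect_false(any(cls2$fourfold[cls2$multi_frame]))
})

test_that("eligibility requires complete unambiguous calls in every sample", {
  reg <- toy_gene_region()
  off <- nchar("ACGTAC")
  cls <- classify_sites(reg$aln, reg$cds)
  base <- eligible_mask(reg$aln, cls, stream = "all4fold")
  expect_true(base[off + 6L])
  # missing call in one sample kills the site
  aln_n <- mutate_at(reg$aln, 2L, off + 6L, "N")
  expect_false(eligible_mask(aln_n, cls, stream = "all4fold")[off + 6L])
  # ambiguity code likewise
  aln_y <- mutate_at(reg$aln, 3L, off + 9L, "Y")
  expect_false(eligible_mask(aln_y, cls, stream = "all4fold")[off + 9L])
  # unpreferred stream is a subset of the 4-fold stream
  up <- eligible_mask(reg$aln, cls, stream = "unpreferred")
  expect_true(all(which(up) %in% which(base)))
  expect_false(up[off + 9L])  # GGC is preferred
  # the two streams coincide when every codon is marked unpreferred
  pref_all <- default_preference_table()
  pref_all$preferred <- FALSE
  cls_all <- classify_sites(reg$aln, reg$cds, pref_all)
  expect_equal(eligible_mask(reg$aln, cls_all, stream = "unpreferred"),
               eligible_mask(reg$aln, cls_all, stream = "all4fold"))
})

test_that("pairwise diversity matches the closed form i(n-i)/C(n,2)", {
  # 4 sequences, 2/2 split at one site -> 4/6 pairs differ
  aln <- c("AAAA", "AAAA", "AATA", "AATA")
  d <- pairwise_diversity(aln)
  expect_equal(unname(d$per_site["3"]), 4 / 6)
  # general biallelic closed form at random allele counts
  set.seed(4)
  for (n in c(3, 5, 8)) {
    for (i in 1:(n - 1)) {
      col <- c(rep("A", i), rep("C", n - i))
      aln1 <- vapply(col, function(b) paste0(b, "A"), character(1L))
      d1 <- pairwise_diversity(aln1)
      expect_equal(unname(d1$per_site["1"]), i * (n - i) / choose(n, 2))
    }
  }
  # 2 sequences, 1 difference among 100 sites
  s1 <- paste(rep("A", 100), collapse = ""); s2 <- s1
  substr(s2, 50, 50) <- "G"
  expect_equal(pairwise_diversity(c(s1, s2))$mean, 0.01)
  expect_equal(pairwise_diversity(c(s1, s1))$mean, 0)
  expect_error(pairwise_diversity(s1), "at least 2")
})

test_that("polymorphic counts match a brute-force column scan", {
  expect_equal(polymorphic_fraction(c("AAAA", "AAAA"))[["polymorphic"]], 0L)
  set.seed(12)
  for (rep in 1:10) {
    m <- matrix(sample(c("A", "C", "G", "T"), 6 * 40, replace = TRUE,
                       prob = c(0.85, 0.05, 0.05, 0.05)), 6, 40)
    aln <- apply(m, 1L, paste, collapse = "")
    pf <- polymorphic_fraction(aln)
    brute <- sum(vapply(seq_len(40), function(j)
      length(unique(m[, j])) >= 2L, logical(1L)))
    expect_equal(unname(pf["polymorphic"]), brute)
    expect_equal(unname(pf["eligible"]), 40L)
  }
})

test_that("between-species divergence behaves like a cross-pairing of diversity", {
  s1 <- paste(rep("A", 300), collapse = ""); s2 <- s1
  for (p in c(10, 150, 299)) substr(s2, p, p) <- "T"
  expect_equal(pairwise_divergence(s1, s2)$mean, 0.01)
  # identical sets: cross-species pairing reduces to the within-set value
  aln <- c("AATA", "AAAA", "AATA", "ACAA")
  expect_equal(pairwise_divergence(aln, aln)$mean,
               mean(recmapsel:::site_pair_diff(recmapsel:::aln_matrix(aln)) *
                      choose(4, 2) * 2 / 16))
  # invariance under sample order
  expect_equal(pairwise_divergence(aln[c(2, 1, 4, 3)], rev(aln))$mean,
               pairwise_divergence(aln, aln)$mean)
  expect_error(pairwise_divergence(character(0), s1), "at least 1")
})

test_that("GC content and gene density are exact base-count proportions", {
  expect_equal(gc_content("GGCCGC"), 1)
  expect_equal(gc_content("ATATAT"), 0)
  expect_equal(gc_content("GATC"), 0.5)
  expect_equal(gc_content("GANNTC", 1, 6), 0.5)  # ambiguous bases ignored
  cds <- data.frame(start = 1L, end = 50L)
  expect_equal(gene_density_interval(cds, 1, 100), 0.5)
  expect_error(gene_density_interval(cds, 10, 5), "zero-length")
  # overlapping segments count once (union), checked against a base-level scan
  set.seed(9)
  for (rep in 1:10) {
    s <- sample(1:80, 6); e <- pmin(100L, s + sample(5:30, 6))
    cds2 <- data.frame(start = s, end = e)
    covered <- logical(100)
    for (k in 1:6) covered[s[k]:e[k]] <- TRUE
    expect_equal(gene_density_interval(cds2, 1, 100), mean(covered))
  }
  # flank density truncates at chromosome ends and flags it
  # window [1, 80] after truncation at the left end; 50 of 80 bases coding
  gd <- gene_density_flank(30L, cds, flank = 50L, chrom_len = 100L)
  expect_equal(as.numeric(gd), 50 / 80)
  expect_true(attr(gd, "truncated"))
})

test_that("interval summaries assemble counts, covariates and the neutral proxy", {
  reg <- toy_gene_region(codons = c("ATG", "GCT", "GCA", "GGA", "CTA", "TAA"),
                         nsamp = 7)
  off <- nchar("ACGTAC")
  aln <- reg$aln
  aln <- mutate_at(aln, 2L, off + 6L, "C")   # polymorphism in focal species
  aln <- mutate_at(aln, 6L, off + 9L, "G")   # divergence in the other species
  aln <- mutate_at(aln, 7L, off + 12L, "T")  # proxy-pair divergence
  species <- c("pse", "pse", "pse", "pse", "mir", "mir", "low")
  # proxy pair = (mir sample, low sample) stands in for the outgroup pair
  iv <- data.frame(left = 1L, right = nchar(aln[1L]), rate = 2.5)
  sm <- interval_summaries(aln, species, reg$cds, iv,
                           focal = "pse", diverged = "mir",
                           proxy_pair = c("mir", "low"),
                           stream = "all4fold")
  expect_equal(sm$polymorphic, 1L)
  expect_gt(sm$divergence, 0)
  expect_gt(sm$mu, 0)
  expect_equal(sm$rate, 2.5)
  expect_true(sm$gc >= 0 && sm$gc <= 1)
  expect_true(sm$gene_density > 0 && sm$gene_density < 1)
  expect_true(sm$polymorphic <= sm$eligible)
  # restricting samples never increases the eligible count
  sm2 <- interval_summaries(aln[1:6], species[1:6], reg$cds, iv,
                            focal = "pse", diverged = "mir",
                            proxy_pair = c("mir", "low"),
                            stream = "all4fold")
  expect_gte(sm2$eligible, sm$eligible)
})
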