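test_that("strong m6ACE enrichment is detected with the expected log2FC", {
  counts <- triplicate_counts("chrT", "+", 20L,
                              m6ace = matrix(c(100, 120, 110), 1),
                              input = matrix(c(10, 12, 11), 1))
  tab <- make_table(counts, library_sizes = stats::setNames(
    rep(1e5, 6), names(counts)[-(1:3)]))
  res <- test_enrichment(tab)
  # point estimate log2(110/11) = 3.32, damped slightly by the 0.5
  # pseudocount on both means
  expect_equal(res$log2FC, log2(110.5 / 11.5), tolerance = 1e-8)
  expect_gt(res$log2FC, 3.2)
  expect_true(res$enriched)
  expect_identical(res$filter_status, "pass")
  # a single tested site: padj equals p
  expect_identical(res$padj, res$p_value)
  expect_lt(res$p_value, 0.05)
})

test_that("identical m6ACE and input counts are never enriched", {
  m <- matrix(c(50, 55, 45), 1)
  counts <- triplicate_counts("chrT", "+", 20L, m6ace = m, input = m)
  tab <- make_table(counts, library_sizes = stats::setNames(
    rep(1e5, 6), names(counts)[-(1:3)]))
  res <- test_enrichment(tab)
  expect_equal(res$log2FC, 0, tolerance = 1e-9)
  expect_false(res$enriched)
  expect_gte(res$p_value, 0.25)
})

test_that("enrichment p-values are calibrated under a Poisson null", {
  set.seed(101)
  n <- 2000
  counts <- triplicate_counts("chrT", "+", seq_len(n) * 10L,
                              m6ace = matrix(rpois(3 * n, 20), n),
                              input = matrix(rpois(3 * n, 20), n))
  tab <- make_table(counts, library_sizes = stats::setNames(
    rep(1e6, 6), names(counts)[-(1:3)]))
  res <- test_enrichment(tab)
  fp <- mean(res$p_value < 0.05)
  expect_gte(fp, 0.03)
  expect_lte(fp, 0.07)
})

test_that("zero library sizes and empty candidate tables are rejected", {
  counts <- triplicate_counts("chrT", "+", 20L,
                              m6ace = matrix(1, 1, 3),
                              input = matrix(1, 1, 3))
  tab <- make_table(counts)
  tab$library_sizes["rep1:input"] <- 0
  expect_error(test_enrichment(tab), "library size")
  tab2 <- make_table(counts)
  tab2$counts <- tab2$counts[0]
  expect_error(test_enrichment(tab2), "no candidate")
})

test_that("shadow filter removes sites 1-4 nt upstream of an RAC site", {
  for (off in 1:4) {
    fx <- shadow_fixture(neighbour_pos = 100L + off)
    out <- filter_shadow_sites(fx$sites, fx$ref)
    expect_identical(out$filter_status[1], "shadow_filtered",
                     label = paste("offset", off))
    expect_identical(out$filter_status[2], "pass")
  }
  # offset 5 is outside the shadow range
  fx <- shadow_fixture(neighbour_pos = 105L)
  expect_identical(filter_shadow_sites(fx$sites, fx$ref)$filter_status,
                   c("pass", "pass"))
})

test_that("shadow filter requires the neighbour's RAC context", {
  # neighbour at +2 but its +1 base is A, not C ("TAA" context)
  fx <- shadow_fixture(neighbour_pos = 102L, context = "TAA")
  out <- filter_shadow_sites(fx$sites, fx$ref)
  expect_identical(out$filter_status, c("pass", "pass"))
})

test_that("shadow filter is strand-aware", {
  # minus strand: shadow sites are 1-4 nt at *higher* genomic
  # coordinates; build the mirror of the plus-strand fixture
  fx <- shadow_fixture(neighbour_pos = 103L)
  ref_m <- mirror_reference(fx$ref)
  sites_m <- fx$sites
  sites_m$pos <- mirror_pos(fx$sites$pos, fx$sites$contig, fx$ref)
  sites_m$strand <- "-"
  sites_m$site_id <- paste(sites_m$contig, sites_m$pos, sites_m$strand,
                           sep = ":")
  out <- filter_shadow_sites(sites_m, ref_m)
  expect_identical(out$filter_status, c("shadow_filtered", "pass"))
})

test_that("cluster filter marks dominated sites inside diffuse clusters", {
  site <- data.frame(contig = "chrT", strand = "+", pos = 100L,
                     site_id = "chrT:100:+", log2FC = 3, p_value = 1e-6,
                     padj = 1e-5, enriched = TRUE, filter_status = "pass",
                     stringsAsFactors = FALSE)
  # isolated pileup: every count in the window is at the site itself
  tab <- cluster_fixture(50L, integer(0), 0L)
  expect_identical(filter_clustered_noise(site, tab)$filter_status, "pass")
  # 20 distinct noise positions, site holds ~5% of the window counts
  noise_pos <- setdiff(seq(80L, 120L, by = 2L), 96:100)
  tab <- cluster_fixture(5L, noise_pos, 5L)
  expect_identical(filter_clustered_noise(site, tab)$filter_status,
                   "cluster_filtered")
  # same cluster but the site dominates (80% of counts) -> kept
  tab <- cluster_fixture(400L, noise_pos, 5L)
  expect_identical(filter_clustered_noise(site, tab)$filter_status, "pass")
})

test_that("cluster filter does not count a nearby enriched site as noise", {
  # two genuine sites 15 nt apart, sharp pileups, light background
  sites <- data.frame(
    contig = "chrT", strand = "+", pos = c(100L, 115L),
    site_id = c("chrT:100:+", "chrT:115:+"), log2FC = c(4, 4),
    p_value = c(1e-8, 1e-8), padj = c(1e-7, 1e-7),
    enriched = c(TRUE, TRUE), filter_status = c("pass", "pass"),
    stringsAsFactors = FALSE)
  bg_pos <- setdiff(seq(76L, 140L, by = 3L), c(100L, 115L))
  counts <- data.frame(contig = "chrT", strand = "+",
                       pos = c(100L, 115L, bg_pos), stringsAsFactors = FALSE)
  counts[["rep1:m6ACE"]] <- c(100L, 100L, rep(2L, length(bg_pos)))
  counts[["rep1:input"]] <- 1L
  out <- filter_clustered_noise(sites, make_table(counts))
  expect_identical(out$filter_status, c("pass", "pass"))
})

test_that("shadow and cluster filters only mark and therefore commute", {
  sc <- cached_scenario("basic", 1)
  res <- cached_call("basic", 1)
  tab <- res$table
  base <- test_enrichment(candidate_sites(tab, sc$reference))
  a <- filter_clustered_noise(filter_shadow_sites(base, sc$reference), tab)
  b <- filter_shadow_sites(filter_clustered_noise(base, tab), sc$reference)
  expect_identical(a$filter_status, b$filter_status)
  expect_true(all(base$filter_status[!base$enriched] == "not_enriched"))
})

test_that("raising min_fold or lowering padj_cutoff shrinks the pass set", {
  sc <- cached_scenario("basic", 1)
  reads <- sc$reads$WT
  base <- call_sites(reads, sc$reference, enrichment_config())
  strict_fold <- call_sites(reads, sc$reference,
                            enrichment_config(min_fold = 4))
  strict_padj <- call_sites(reads, sc$reference,
                            enrichment_config(padj_cutoff = 0.001))
  expect_true(all(strict_fold$pass$site_id %in% base$pass$site_id))
  expect_true(all(strict_padj$pass$site_id %in% base$pass$site_id))
})

test_that("the pass set is exactly mirrored in the reverse-complement world", {
  sc <- cached_scenario("basic", 1)
  res <- cached_call("basic", 1)
  reads_m <- mirror_reads(deduplicate(sc$reads$WT), sc$reference)
  ref_m <- mirror_reference(sc$reference)
  res_m <- call_sites(reads_m, ref_m)
  expect_identical(
    sort(paste(res_m$pass$contig,
               mirror_pos(res_m$pass$pos, res_m$pass$contig, sc$reference))),
    sort(paste(res$pass$contig, res$pass$pos)))
  expect_true(all(res_m$pass$strand == "-"))
})

test_that("site ids are stable across repeated calls on the same input", {
  res1 <- cached_call("basic", 1)
  sc <- cached_scenario("basic", 1)
  res2 <- call_sites(sc$reads$WT, sc$reference)
  expect_identical(res1$sites$site_id, res2$sites$site_id)
  expect_identical(res1$pass, res2$pass)
})
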