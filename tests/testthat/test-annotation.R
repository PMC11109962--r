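two_gene_models <- function() {
  dplyr::bind_rows(
    toy_gene("gA", "chr1", 10000L, 30000L, "+",
             exons = tibble::tibble(start = c(10000L, 29000L),
                                    end = c(10400L, 30000L))),
    toy_gene("gB", "chr1", 60000L, 80000L, "-")
  )
}

test_that("distance to the nearest TSS is signed by gene strand", {
  genes <- two_gene_models()
  # midpoint 10500, plus-strand TSS 10000 -> +500 downstream
  s <- toy_site("s1", "chr1", 10400L, 10600L)
  d <- distance_to_tss(s, genes)
  expect_equal(d$gene_id, "gA")
  expect_equal(d$tss_distance, 500L)
  # midpoint 79000 near the minus-strand TSS at 79999 -> downstream (+999)
  s2 <- toy_site("s2", "chr1", 78900L, 79100L)
  d2 <- distance_to_tss(s2, genes)
  expect_equal(d2$gene_id, "gB")
  expect_equal(d2$tss_distance, 999L)
  # nearest by absolute distance wins
  s3 <- toy_site("s3", "chr1", 44000L, 44200L)  # 34100 from gA, 35899 from gB
  expect_equal(distance_to_tss(s3, genes)$gene_id, "gA")
  # no gene on chromosome -> NA sentinel
  expect_true(is.na(distance_to_tss(toy_site("s", "chrZ", 0L, 10L),
                                    genes)$gene_id))
})

test_that("ties in nearest TSS break on the smaller gene_id", {
  genes <- dplyr::bind_rows(
    toy_gene("gZ", "chr1", 1000L, 2000L, "+"),
    toy_gene("gA", "chr1", 3000L, 4000L, "+"))
  # midpoint 2000: 1000 from both TSSs
  d <- distance_to_tss(toy_site("s", "chr1", 1950L, 2050L), genes)
  expect_equal(d$gene_id, "gA")
})

test_that("categorization follows the documented precedence", {
  genes <- two_gene_models()
  expect_equal(categorize_site(toy_site("s", "chr1", 10000L, 10200L), genes),
               "promoter")
  # inside the gene but 20 kb from the TSS: gene body (intron/exon merged)
  expect_equal(categorize_site(toy_site("s", "chr1", 29500L, 29700L),
                               genes, promoter_window = c(3000L, 3000L)),
               "gene_body")
  # past the gene end within the window: downstream
  expect_equal(categorize_site(toy_site("s", "chr1", 31000L, 31200L), genes),
               "downstream")
  # far from every gene: intergenic
  expect_equal(categorize_site(toy_site("s", "chr1", 45000L, 45200L), genes),
               "intergenic")
  # annotated 5' UTR outranks gene body
  g_utr <- dplyr::bind_rows(
    toy_gene("gU", "chr2", 100000L, 120000L, "+",
             utr5 = tibble::tibble(start = 104000L, end = 104500L)))
  expect_equal(categorize_site(toy_site("s", "chr2", 104100L, 104300L),
                               g_utr), "five_prime_utr")
})

test_that("vectorized annotation agrees with the per-site reference path", {
  withr::with_seed(31, {
    genes <- dplyr::bind_rows(
      toy_gene("g1", "chr1", 5000L, 15000L, "+"),
      toy_gene("g2", "chr1", 40000L, 52000L, "-",
               utr3 = tibble::tibble(start = 40000L, end = 40800L)),
      toy_gene("g3", "chr2", 9000L, 21000L, "+"))
    sites <- tibble::tibble(
      site_id = sprintf("s%03d", 1:120),
      chrom = sample(c("chr1", "chr2"), 120, replace = TRUE),
      start = sample.int(60000L, 120))
    sites$end <- sites$start + 200L
    ann <- annotate_sites(sites, genes)
    expect_equal(nrow(ann), 120)
    expect_false(anyNA(ann$category))
    for (i in seq_len(nrow(sites))) {
      s <- sites[i, ]
      expect_equal(as.character(ann$category[i]), categorize_site(s, genes))
      ref <- distance_to_tss(s, genes)
      expect_equal(ann$nearest_gene[i], ref$gene_id)
      expect_equal(ann$tss_distance[i], ref$tss_distance)
    }
  })
})

test_that("TSS distances are invariant under a constant coordinate shift", {
  genes <- two_gene_models()
  sites <- tibble::tibble(site_id = c("a", "b"), chrom = "chr1",
                          start = c(12000L, 70000L), end = c(12300L, 70300L))
  shift <- 12345L
  genes2 <- genes |>
    dplyr::mutate(start = start + shift, end = end + shift,
                  tss = tss + shift)
  sites2 <- dplyr::mutate(sites, start = start + shift, end = end + shift)
  expect_equal(annotate_sites(sites, genes)$tss_distance,
               annotate_sites(sites2, genes2)$tss_distance)
})

test_that("basal-plus-extension association matches explicit domain materialization", {
  # hand-checked basal containment: plus-strand TSS 10000, basal [5000, 11000]
  g <- toy_gene("gA", "chr1", 10000L, 20000L, "+")
  hit <- associate_genes(toy_site("s", "chr1", 6900L, 7100L), g)
  expect_equal(hit$gene_id, "gA")
  # a lone gene extends up to 1 Mb: midpoint 400 kb away is still associated
  far <- associate_genes(toy_site("s", "chr1", 409900L, 410100L), g)
  expect_equal(far$gene_id, "gA")
  beyond <- associate_genes(toy_site("s", "chr1", 1200000L, 1200200L), g)
  expect_equal(nrow(beyond), 0)
  # extension stops at the neighbour's basal domain
  genes <- dplyr::bind_rows(
    g, toy_gene("gB", "chr1", 200000L, 210000L, "+"))
  # midpoint 197000 sits inside gB's basal domain [195000, 201000] only
  inb <- associate_genes(toy_site("s", "chr1", 196900L, 197100L), genes)
  expect_equal(inb$gene_id, "gB")
  # randomized toy genomes against the O(n*m) oracle
  withr::with_seed(32, {
    for (trial in 1:4) {
      n_genes <- sample(10:30, 1)
      gstart <- sort(sample.int(2000000L, n_genes))
      genes_r <- dplyr::bind_rows(lapply(seq_len(n_genes), function(i) {
        toy_gene(sprintf("g%02d", i), "chr1", gstart[i],
                 gstart[i] + sample(2000:20000, 1),
                 sample(c("+", "-"), 1))
      }))
      sites_r <- tibble::tibble(
        site_id = sprintf("s%03d", 1:80), chrom = "chr1",
        start = sample.int(2200000L, 80))
      sites_r$end <- sites_r$start + 300L
      got <- associate_genes(sites_r, genes_r) |>
        dplyr::arrange(site_id, gene_id)
      exp <- oracle_associations(sites_r, genes_r)
      expect_equal(got$site_id, exp$site_id)
      expect_equal(got$gene_id, exp$gene_id)
    }
  })
})

test_that("shrinking the extension cap never adds associations", {
  withr::with_seed(33, {
    genes <- dplyr::bind_rows(lapply(1:12, function(i) {
      s <- i * 150000L
      toy_gene(sprintf("g%02d", i), "chr1", s, s + 8000L,
               sample(c("+", "-"), 1))
    }))
    sites <- tibble::tibble(site_id = sprintf("s%03d", 1:60), chrom = "chr1",
                            start = sample.int(2000000L, 60))
    sites$end <- sites$start + 200L
    key <- function(a) paste(a$site_id, a$gene_id)
    a_full <- associate_genes(sites, genes, max_extension = 1000000L)
    a_mid <- associate_genes(sites, genes, max_extension = 100000L)
    a_small <- associate_genes(sites, genes, max_extension = 10000L)
    expect_true(all(key(a_mid) %in% key(a_full)))
    expect_true(all(key(a_small) %in% key(a_mid)))
  })
})

test_that("overlap_fraction counts sites touching the other set", {
  a <- tibble::tibble(chrom = "chr1", start = c(0L, 100L, 200L, 300L),
                      end = c(50L, 150L, 250L, 350L))
  b_far <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1100L)
  expect_equal(overlap_fraction(a, b_far)$fraction, 0)
  expect_equal(overlap_fraction(a, a)$fraction, 1)
  b3 <- tibble::tibble(chrom = "chr1", start = c(10L, 120L, 210L),
                       end = c(20L, 130L, 220L))
  of <- overlap_fraction(a, b3)
  expect_equal(of$n_overlap, 3L)
  expect_equal(of$fraction, 0.75)
  expect_warning(res <- overlap_fraction(a[0, ], b3), "empty")
  expect_true(is.nan(res$fraction))
})
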