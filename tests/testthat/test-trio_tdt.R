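one_snp_map <- "1\trs1\t0\t100"

test_that("transmission counting follows the standard per-parent rules", {
  # only the heterozygous father is informative; he transmitted A
  f <- write_ped_map(c("F1 DAD 0 0 1 1 A B",
                       "F1 MOM 0 0 2 1 A A",
                       "F1 KID DAD MOM 1 2 A A"), one_snp_map)
  panel <- read_trios(f$ped, f$map)
  expect_equal(nrow(panel$trios), 1L)
  tc <- count_transmissions(panel, "rs1")
  expect_equal(tc$b, 1L)
  expect_equal(tc$c, 0L)

  # het x het -> het resolves as one transmission of each allele
  f <- write_ped_map(c("F1 DAD 0 0 1 1 A B",
                       "F1 MOM 0 0 2 1 A B",
                       "F1 KID DAD MOM 1 2 A B"), one_snp_map)
  tc <- count_transmissions(read_trios(f$ped, f$map), "rs1")
  expect_equal(c(tc$b, tc$c), c(1L, 1L))

  # no heterozygous parent: uninformative
  f <- write_ped_map(c("F1 DAD 0 0 1 1 A A",
                       "F1 MOM 0 0 2 1 B B",
                       "F1 KID DAD MOM 1 2 A B"), one_snp_map)
  tc <- count_transmissions(read_trios(f$ped, f$map), "rs1")
  expect_equal(c(tc$b, tc$c), c(0L, 0L))

  expect_error(count_transmissions(read_trios(f$ped, f$map), "rs99"),
               class = "cleftminer_lookup_error")
})

test_that("Mendelian-inconsistent and missing trios are excluded per SNP", {
  f <- write_ped_map(c("F1 DAD 0 0 1 1 A A",
                       "F1 MOM 0 0 2 1 A B",
                       "F1 KID DAD MOM 1 2 B B",   # impossible given AA father
                       "F2 DAD 0 0 1 1 A B",
                       "F2 MOM 0 0 2 1 A A",
                       "F2 KID DAD MOM 1 2 0 0"),  # missing child genotype
                     one_snp_map)
  panel <- read_trios(f$ped, f$map)
  expect_message(tc <- count_transmissions(panel, "rs1"), "Mendelian")
  expect_equal(tc$n_mendel_errors, 1L)
  expect_equal(c(tc$b, tc$c), c(0L, 0L))
})

test_that("pedigree parsing handles orphans, singletons and malformed files", {
  f <- write_ped_map(c("F1 KID DAD MOM 1 2 A A",
                       "F1 MOM 0 0 2 1 A A"), one_snp_map)
  expect_warning(expect_warning(panel <- read_trios(f$ped, f$map), "absent"),
                 "no complete")
  expect_equal(nrow(panel$trios), 0L)

  f <- write_ped_map(c("F1 IND1 0 0 1 1 A A",
                       "F2 IND2 0 0 2 1 A B"), one_snp_map)
  expect_warning(panel <- read_trios(f$ped, f$map), "no complete")
  expect_equal(nrow(panel$trios), 0L)

  f <- write_ped_map("F1 IND1 0 0 1 1 A A B",  # 3 allele fields for 1 SNP
                     one_snp_map)
  expect_error(read_trios(f$ped, f$map), class = "cleftminer_format_error")
})

test_that("multiallelic SNPs are dropped with a warning", {
  f <- write_ped_map(c("F1 DAD 0 0 1 1 A B G G",
                       "F1 MOM 0 0 2 1 A A G T",
                       "F1 KID DAD MOM 1 2 A A G C"),
                     c("1\trs1\t0\t100", "1\trs2\t0\t200"))
  expect_warning(panel <- read_trios(f$ped, f$map), "multiallelic")
  expect_equal(panel$snps$id, "rs1")
})

test_that("a simulated panel round-trips through PED/MAP text losslessly", {
  spec <- synthetic_spec(seed = 13, n_trios = 50, n_snps = 8, maf = 0.4)
  panel <- simulate_trios(spec)
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  write_trios(panel, ped, map)
  back <- read_trios(ped, map)
  expect_identical(back$snps, panel$snps)
  expect_identical(back$trios, panel$trios)
  expect_identical(back$father, panel$father)
  expect_identical(back$mother, panel$mother)
  expect_identical(back$child, panel$child)
})

test_that("the TDT statistic matches closed forms and the McNemar oracle", {
  expect_equal(tdt_statistic(10, 10), list(chi2 = 0, p = 1))
  st <- tdt_statistic(20, 5)
  expect_equal(st$chi2, 9)
  expect_equal(st$p, 0.0026998, tolerance = 1e-4)
  st <- tdt_statistic(1, 0)
  expect_equal(st$chi2, 1)
  expect_equal(st$p, 0.3173105, tolerance = 1e-6)
  expect_error(tdt_statistic(0, 0), class = "cleftminer_uninformative_error")
  expect_error(tdt_statistic(-1, 2), class = "cleftminer_domain_error")

  set.seed(51)
  b <- rpois(2000, 20); c <- rpois(2000, 15)
  keep <- b + c > 0
  st <- tdt_statistic(b[keep], c[keep])
  oracle <- vapply(which(keep), function(i) {
    m <- stats::mcnemar.test(matrix(c(0, b[i], c[i], 0), 2), correct = FALSE)
    c(unname(m$statistic), m$p.value)
  }, numeric(2))
  expect_equal(st$chi2, oracle[1, ], tolerance = 1e-12)
  expect_equal(st$p, oracle[2, ], tolerance = 1e-12)
})

test_that("swapping allele labels swaps b and c but leaves chi2 and p unchanged", {
  spec <- synthetic_spec(seed = 17, n_trios = 80, n_snps = 10, tau = 0.7)
  panel <- simulate_trios(spec)
  swapped <- panel
  swapped$father <- 2L - panel$father
  swapped$mother <- 2L - panel$mother
  swapped$child <- 2L - panel$child
  for (s in panel$snps$id) {
    a <- count_transmissions(panel, s)
    d <- count_transmissions(swapped, s)
    expect_equal(c(a$b, a$c), c(d$c, d$b))
    expect_equal(tdt_statistic(a$b, a$c), tdt_statistic(d$b, d$c))
  }
})

test_that("SNPs map to genes under BED half-open, 1-based MAP conventions", {
  bed <- write_tmp_tsv(c("1\t99\t100\tGENE_EDGE",
                         "1\t100\t200\tGENE_RIGHT",
                         "1\t500\t600\tGENE_FAR"), ext = ".bed")
  snps <- data.frame(id = c("rs1", "rs2"), chr = "1", pos = c(100L, 450L))
  a0 <- assign_genes(snps, bed, flank_bp = 0)
  expect_equal(a0$rs1, "GENE_EDGE")   # BED [99,100) contains 0-based 99
  expect_equal(a0$rs2, character(0))

  a1k <- assign_genes(snps, bed, flank_bp = 100)
  expect_true(all(a0$rs1 %in% a1k$rs1))  # flanking is monotone
  expect_equal(a1k$rs2, "GENE_FAR")

  expect_error(assign_genes(snps, "no/such.bed"),
               class = "cleftminer_format_error")
})

test_that("the scan reports per-SNP and top-marker-per-gene tables with tiers", {
  spec <- synthetic_spec(seed = 19, n_trios = 300, n_snps = 12, maf = 0.3,
                         distorted_snps = data.frame(snp = 4, tau = 0.9))
  panel <- simulate_trios(spec)
  assignment <- setNames(c(rep(list("GENE_A"), 6), rep(list("GENE_B"), 5),
                           list(character(0))), panel$snps$id)
  scan <- tdt_scan(panel, gene_assignment = assignment, alpha = 0.05)

  expect_true(all(scan$per_snp$b + scan$per_snp$c > 0))
  expect_equal(scan$tiers$candidate_wise, 0.05 / 2)
  expect_equal(scan$per_gene$gene[1], "GENE_A")
  expect_equal(scan$per_gene$top_marker[1], "rs000004")
  expect_true(all(scan$per_gene$p ==
                    vapply(scan$per_gene$gene, function(g) {
                      hit <- grepl(g, scan$per_snp$gene, fixed = TRUE)
                      min(scan$per_snp$p[hit])
                    }, 1.0)))
  # rs000012 is assigned to no gene: present per SNP, absent per gene
  expect_true("rs000012" %in% scan$per_snp$snp ||
                sum(panel$father[12, ] == 1 | panel$mother[12, ] == 1) == 0)
  expect_setequal(scan$per_gene$gene, c("GENE_A", "GENE_B"))
})

test_that("power grows with transmission distortion and with trio count", {
  seeds <- 1:40
  power_at <- function(tau, n_trios) {
    mean(vapply(seeds, function(s) {
      panel <- simulate_trios(synthetic_spec(seed = 300 + s, n_trios = n_trios,
                                             n_snps = 1, maf = 0.3, tau = tau))
      tc <- count_transmissions(panel, panel$snps$id[1])
      if (tc$b + tc$c == 0) return(FALSE)
      tdt_statistic(tc$b, tc$c)$p < 0.05
    }, logical(1)))
  }
  by_tau <- vapply(c(0.55, 0.65, 0.75), power_at, 1.0, n_trios = 200)
  expect_true(all(diff(by_tau) >= 0))
  by_n <- vapply(c(50, 150, 400), function(n) power_at(0.62, n), 1.0)
  expect_true(all(diff(by_n) >= 0))
})

test_that("Bonferroni thresholds divide alpha by the genes tested", {
  expect_equal(signif(bonferroni_threshold(0.05, 179), 3), 2.79e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 1000), 5e-5)
  expect_error(bonferroni_threshold(1.5, 10), class = "cleftminer_domain_error")
  expect_error(bonferroni_threshold(0.05, 0), class = "cleftminer_domain_error")

  tiers <- significance_tiers(n_genes = 179)
  expect_lt(tiers$genome_wide, tiers$gene_wide)
  expect_lt(tiers$gene_wide, tiers$candidate_wise)
})
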