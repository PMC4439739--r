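quant_tbl <- function(peptide, protein, fraction, heavy, light) {
  tibble::tibble(peptide = peptide, protein = protein, fraction = fraction,
                 heavy_intensity = heavy, light_intensity = light)
}

test_that("gel-slice calibration maps masses as expected", {
  cal <- calibrate_fractions()
  s <- mass_to_slice(cal, c(1000, 700, 10))
  expect_equal(as.integer(s), c(1L, 3L, 20L))
  expect_equal(attr(s, "clamped"), c(FALSE, FALSE, TRUE))
  expect_error(mass_to_slice(cal, -5), "positive")
  expect_error(calibrate_fractions(mass_top = 60, mass_bottom = 1000), "exceed")
  expect_error(calibrate_fractions(n_slices = 1), "n_slices")
})

test_that("per-fraction ratios are summed-intensity quotients", {
  q <- quant_tbl(c("p1", "p2"), "X", 3, c(100, 300), c(50, 150))
  prof <- protein_fraction_ratios(q)
  expect_equal(unname(prof$ratios["X", 3]), 2.0)
  expect_true(all(is.na(prof$ratios["X", -3])))

  # 1:1 mixing gives ratio 1 in every quantified fraction
  q2 <- quant_tbl(rep(c("p1", "p2"), 3), "Y", rep(1:3, each = 2),
                  c(10, 20, 30, 40, 50, 60), c(10, 20, 30, 40, 50, 60))
  prof2 <- protein_fraction_ratios(q2)
  expect_equal(unname(prof2$ratios["Y", 1:3]), rep(1, 3))

  # heavy-only cells cap and flag
  q3 <- quant_tbl("p", "Z", 5, 500, 0)
  prof3 <- protein_fraction_ratios(q3)
  expect_equal(unname(prof3$ratios["Z", 5]), 100)
  expect_true(prof3$capped["Z", 5])
})

test_that("ratios are invariant to common scaling of both channels", {
  set.seed(9)
  q <- quant_tbl(sprintf("p%d", 1:12), rep(c("A", "B"), 6),
                 sample(1:20, 12, replace = TRUE),
                 runif(12, 1, 100), runif(12, 1, 100))
  fac <- runif(12, 0.1, 10)
  q2 <- q
  q2$heavy_intensity <- q2$heavy_intensity * fac
  q2$light_intensity <- q2$light_intensity * fac
  # scaling a peptide's both channels by one factor leaves the median-of-ratios
  # per-peptide ratios unchanged
  p1 <- protein_fraction_ratios(q, method = "median")
  p2 <- protein_fraction_ratios(q2, method = "median")
  expect_equal(p1$ratios, p2$ratios)
  # and a global common factor leaves summed-intensity ratios unchanged too
  q3 <- q
  q3$heavy_intensity <- q3$heavy_intensity * 3.7
  q3$light_intensity <- q3$light_intensity * 3.7
  expect_equal(protein_fraction_ratios(q)$ratios,
               protein_fraction_ratios(q3)$ratios)
})

test_that("protein fraction ratio lies within its peptides' ratio range", {
  set.seed(13)
  for (rep in 1:10) {
    n_pep <- sample(2:6, 1)
    q <- quant_tbl(sprintf("p%d", seq_len(n_pep)), "A", 4,
                   runif(n_pep, 1, 50), runif(n_pep, 1, 50))
    prof <- protein_fraction_ratios(q)
    pr <- q$heavy_intensity / q$light_intensity
    expect_gte(prof$ratios["A", 4], min(pr))
    expect_lte(prof$ratios["A", 4], max(pr))
  }
})

test_that("total-abundance ratios sum each peptide across fractions", {
  q <- quant_tbl("pep", "A", 1:3, c(10, 20, 30), c(30, 40, 50))
  tot <- total_abundance_ratios(q)
  expect_equal(tot$per_peptide$ratio, 0.5)
  expect_equal(tot$per_protein$ratio, 0.5)

  eq <- quant_tbl("pep", "A", 1:2, c(5, 15), c(15, 5))
  expect_equal(total_abundance_ratios(eq)$per_protein$ratio, 1)

  light_only <- quant_tbl("pep", "A", 1, 0, 8)
  expect_equal(total_abundance_ratios(light_only)$per_peptide$ratio, 0)
})

test_that("per-protein totals recombine the fraction ratios by light weights", {
  set.seed(31)
  q <- quant_tbl(sprintf("p%d", 1:30), rep(c("A", "B", "C"), 10),
                 sample(1:20, 30, replace = TRUE),
                 runif(30, 1, 100), runif(30, 1, 100))
  prof <- protein_fraction_ratios(q)
  tot <- total_abundance_ratios(q)
  for (pr in c("A", "B", "C")) {
    r <- prof$ratios[pr, ]
    l <- vapply(seq_along(r), function(fr) {
      sum(q$light_intensity[q$protein == pr & q$fraction == fr])
    }, numeric(1))
    ok <- !is.na(r)
    recombined <- sum(r[ok] * l[ok]) / sum(l[ok])
    expect_equal(recombined, tot$per_protein$ratio[tot$per_protein$protein == pr],
                 tolerance = 1e-12)
  }
})

test_that("detect_shift classifies programmed window patterns", {
  # flat 1.0 everywhere
  flat <- quant_tbl(rep("p", 20), "A", 1:20, rep(10, 20), rep(10, 20))
  prof <- protein_fraction_ratios(flat)
  expect_equal(detect_shift(prof)$call, "no_change")

  # ratio 0.5 in the 700 kDa window (slices 2-4), 2 near 500 kDa (slices 5-6)
  light <- rep(100, 20)
  heavy <- rep(100, 20)
  heavy[2:4] <- 50
  heavy[5:6] <- 200
  shift <- quant_tbl(rep("p", 20), "S", 1:20, heavy, light)
  res <- detect_shift(protein_fraction_ratios(shift))
  expect_equal(res$call, "subcomplex_shift")
  expect_equal(res$mature_log2, -1)
  expect_equal(res$sub_log2, 1)

  # mature depletion with unchanged total: depleted, not degraded
  heavy2 <- rep(100, 20); heavy2[2:4] <- 50; heavy2[10:12] <- 150
  dep <- quant_tbl(rep("p", 20), "D", 1:20, heavy2, light)
  expect_equal(detect_shift(protein_fraction_ratios(dep))$call, "depleted")

  # window with no quantified values
  lonely <- quant_tbl("p", "L", 10, 5, 5)
  expect_equal(detect_shift(protein_fraction_ratios(lonely))$call,
               "insufficient_data")
})

test_that("a degraded knockdown analog is called degraded with the right total", {
  eff <- tibble::tibble(protein = "MIC10", degradation = 0.3)
  sim <- simulate_complexome(complexome_sim_config(effects = eff), seed = 5)
  prof <- protein_fraction_ratios(sim$quants)
  res <- detect_shift(prof)
  expect_equal(res$call, "degraded")
  tot <- total_abundance_ratios(sim$quants)$per_protein$ratio
  expect_lt(abs(tot - 0.3), 0.1)
})

test_that("the heatmap renders and writes to file", {
  eff <- tibble::tibble(protein = c("MIC60", "CTRL"),
                        mature_depletion = c(0.5, 1),
                        sub_accumulation = c(2, 1))
  sim <- simulate_complexome(complexome_sim_config(effects = eff), seed = 6)
  prof <- protein_fraction_ratios(sim$quants)
  p <- render_heatmap(prof)
  expect_s3_class(p, "ggplot")
  expect_equal(nrow(p$data), 2 * 20)
  path <- withr::local_tempfile(fileext = ".png")
  render_heatmap(prof, path)
  expect_true(file.exists(path) && file.size(path) > 0)
})

test_that("peptide quant tables round-trip and support column mapping", {
  q <- quant_tbl(c("p1", "p2"), c("A", "B"), c(3, 7), c(1.5, 2), c(3, 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_quants(q, path)
  expect_equal(as.data.frame(read_peptide_quants(path)), as.data.frame(q))

  # evidence-style headers via col_map
  foreign <- q
  names(foreign) <- c("Sequence", "Proteins", "Fraction", "Intensity H", "Intensity L")
  readr::write_tsv(foreign, path)
  mapped <- read_peptide_quants(path, col_map = c(
    peptide = "Sequence", protein = "Proteins", fraction = "Fraction",
    heavy_intensity = "Intensity H", light_intensity = "Intensity L"))
  expect_equal(as.data.frame(mapped), as.data.frame(q))
})
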