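make_ct <- function(target_ct, ref_ct, zt = seq_along(target_ct) - 1) {
  n <- length(target_ct)
  ids <- sprintf("s%d", seq_len(n))
  rbind(
    data.frame(sample_id = ids, gene = "tgt", zt = zt, replicate = 1,
               ct = target_ct),
    data.frame(sample_id = ids, gene = "ref", zt = zt, replicate = 1,
               ct = ref_ct))
}

test_that("2^-ddCt gives powers of two for integer ddCt", {
  # dCt = 5, 6, 3 against a global-mean calibrator is not integer; use the
  # min calibrator so ddCt = dCt - min(dCt)
  ct <- make_ct(c(25, 26, 23), c(20, 20, 20))
  r <- delta_delta_ct(ct, "tgt", "ref", calibrator = "min")
  expect_equal(r$value, c(2^-2, 2^-3, 1))
  # a sample whose dCt equals the calibrator dCt has R = 1
  ct0 <- make_ct(c(24, 24), c(20, 20))
  expect_equal(delta_delta_ct(ct0, "tgt", "ref")$value, c(1, 1))
})

test_that("ddCt uses the mean Ct of a multi-gene reference set", {
  n <- 3
  ids <- sprintf("s%d", 1:n)
  ct <- rbind(
    data.frame(sample_id = ids, gene = "tgt", zt = 0:2, replicate = 1,
               ct = c(25, 24, 26)),
    data.frame(sample_id = ids, gene = "refA", zt = 0:2, replicate = 1,
               ct = c(20, 20, 20)),
    data.frame(sample_id = ids, gene = "refB", zt = 0:2, replicate = 1,
               ct = c(22, 22, 22)))
  r2 <- delta_delta_ct(ct, "tgt", c("refA", "refB"), calibrator = "min")
  # dCt against mean(20,22)=21: 4, 3, 5 -> ddCt 1, 0, 2
  expect_equal(r2$value, c(0.5, 1, 0.25))
})

test_that("ddCt is invariant to per-sample Ct shifts and validates input", {
  ct <- make_ct(c(25, 26, 23, 27), c(20, 21, 19, 20))
  base <- delta_delta_ct(ct, "tgt", "ref")
  shifted <- ct
  shift <- c(s1 = 1.3, s2 = -0.7, s3 = 2.2, s4 = 0)
  shifted$ct <- shifted$ct + shift[shifted$sample_id]
  expect_equal(delta_delta_ct(shifted, "tgt", "ref")$value, base$value)

  expect_error(delta_delta_ct(ct, "tgt", character(0)), "empty reference")
  expect_error(delta_delta_ct(ct, "nope", "ref"), "nope")
  broken <- ct[!(ct$gene == "ref" & ct$sample_id == "s2"), ]
  expect_error(delta_delta_ct(broken, "tgt", "ref"), "s2")
})

test_that("noiseless synthetic round-trip recovers expression up to a constant", {
  genes <- list(gene_spec("g1", 0.8, 0.3, 1.5, noise_sd = 0),
                gene_spec("ref", 1, 0, noise_sd = 0, role = "reference_stable"))
  des <- study_design(seed = 9)
  ct <- generate_ct_dataset(genes, des)
  truth <- generate_expression_dataset(genes[1], des)
  r <- delta_delta_ct(ct, "g1", "ref")
  ratio <- r$value / truth$value
  expect_lt(diff(range(ratio)), 1e-12)  # single constant factor
})

test_that("geNorm M is zero for exactly proportional genes", {
  q <- cbind(a = c(1, 2, 4, 8), b = 2 * c(1, 2, 4, 8), c = 5 * c(1, 2, 4, 8))
  res <- genorm_m(q)
  expect_equal(unname(res$m_values), c(0, 0, 0))
})

test_that("geNorm M matches the brute-force all-pairs oracle", {
  # hand-checkable 3x4 panel
  q <- cbind(a = c(1, 2, 4, 8), b = c(1, 4, 4, 16), c = c(2, 2, 8, 8))
  res <- genorm_m(q)
  expect_equal(res$m_values, oracle_genorm_m(q), tolerance = 1e-12)

  set.seed(123)
  for (i in 1:12) {
    ng <- sample(3:5, 1); ns <- sample(3:6, 1)
    q <- matrix(sample(1:32, ng * ns, replace = TRUE), ns, ng)
    colnames(q) <- paste0("g", seq_len(ng))
    res <- genorm_m(q)
    oracle <- oracle_genorm_m(q)
    expect_equal(res$m_values, oracle, tolerance = 1e-12)
    expect_equal(res$ranking, names(sort(oracle)))
  }
})

test_that("geNorm is invariant to rescaling one sample", {
  set.seed(4)
  q <- matrix(exp(rnorm(24)), 6, 4, dimnames = list(NULL, letters[1:4]))
  res1 <- genorm_m(q)
  q2 <- q; q2[3, ] <- q2[3, ] * 50
  res2 <- genorm_m(q2)
  expect_equal(res1$m_values, res2$m_values, tolerance = 1e-12)
  expect_equal(res1$pairwise_variation, res2$pairwise_variation,
               tolerance = 1e-12)
})

test_that("a drifting candidate ranks least stable in nearly all replicates", {
  hits <- 0L
  for (s in 1:200) {
    ct <- generate_ct_dataset(reference_panel(), study_design(seed = 9000 + s))
    q <- data.frame(sample_id = ct$sample_id, gene = ct$gene,
                    value = 2^(-ct$ct))
    res <- genorm_m(q)
    if (utils::tail(res$ranking, 1) == "r18s") hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("reference selection follows the V(n/n+1) rule", {
  fake <- structure(list(
    m_values = c(a = 0.1, b = 0.12, c = 0.2, d = 0.3, e = 0.4),
    ranking = c("a", "b", "c", "d", "e"),
    pairwise_variation = c(`V2/3` = 0.3, `V3/4` = 0.12, `V4/5` = 0.08)),
    class = "genorm_result")
  expect_equal(select_reference(fake, mode = "single"), "a")
  expect_equal(select_reference(fake), c("a", "b", "c"))
  allgood <- fake
  allgood$pairwise_variation <- c(`V2/3` = 0.05, `V3/4` = 0.04, `V4/5` = 0.03)
  expect_equal(select_reference(allgood), c("a", "b"))
  allbad <- fake
  allbad$pairwise_variation <- c(`V2/3` = 0.3, `V3/4` = 0.3, `V4/5` = 0.3)
  expect_equal(select_reference(allbad), c("a", "b", "c", "d", "e"))
})

test_that("geNorm rejects invalid input", {
  expect_error(genorm_m(cbind(a = 1:4, b = 1:4)), ">= 3")
  expect_error(genorm_m(cbind(a = c(1, -1, 2), b = 1:3, c = 1:3)), "> 0")
})
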