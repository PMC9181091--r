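test_that("BH adjustment matches hand and oracle computations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)              # m = 1 identity
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))  # cap at 1
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.1, NA)), "0, 1")

  withr::with_seed(51, {
    for (i in 1:50) {
      p <- runif(sample(1:40, 1))
      expect_equal(bh_adjust(p), brute_bh(p))
    }
  })
})

test_that("DE selection splits survivors by effect sign at strict adjusted-p threshold", {
  tb <- data.frame(gene_id = paste0("g", 1:4),
                   effect = c(1, 0.5, -0.5, -1),
                   p_raw = c(0.001, 0.2, 0.3, 0.9))
  sig <- suppressMessages(select_de_genes(tb, alpha = 0.05, dataset_id = "ds"))
  expect_identical(sig$up, "g1")     # BH: 0.004, others >= 0.4
  expect_length(sig$down, 0)

  sig_all <- suppressMessages(select_de_genes(tb, alpha = 1.0))
  expect_setequal(c(sig_all$up, sig_all$down), tb$gene_id)

  tb$p_raw <- rep(0.5, 4)
  expect_warning(suppressMessages(select_de_genes(tb, alpha = 0.05)),
                 "no genes survive")
})

test_that("enrichment score concentrates at the extremes and stays small for spread sets", {
  universe <- sprintf("T%04d", 1:1000)
  sig <- block_signature("d1", universe, top = universe[1:20],
                         bottom = universe[101:120], seed = 61)
  # set = top of the ranking -> strongly positive
  expect_gt(enrichment_score(sig, universe[1:20]), 0.9)
  # set = bottom of the ranking -> strongly negative
  expect_lt(enrichment_score(sig, universe[101:120]), -0.9)
  expect_error(enrichment_score(sig, c("nope1", "nope2")), "intersect")

  # uniformly spread 50-gene set: |ES| stays far below the concentrated
  # extreme (~1). Null medians were frozen from a 200-replicate simulation
  # with an independent GSEA implementation: ~0.25 for the weighted (w = 1)
  # statistic under normal scores, ~0.12 unweighted.
  es_sim <- function(w) {
    vapply(1:15, function(s) {
      withr::with_seed(60 + s, {
        scores <- setNames(rnorm(1000), universe)
        spread <- sample(universe, 50)
        abs(enrichment_score(drug_signature("d", scores), spread, weight = w))
      })
    }, numeric(1))
  }
  expect_lt(median(es_sim(1)), 0.35)
  expect_lt(median(es_sim(0)), 0.2)
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  withr::with_seed(71, {
    for (i in 1:20) {
      L <- sample(50:300, 1)
      genes <- sprintf("g%04d", 1:L)
      scores <- setNames(rnorm(L), genes)
      set <- sample(genes, sample(3:15, 1))
      sig <- drug_signature("d", scores)
      idx <- match(intersect(sig$genes, set), sig$genes)
      want <- fgsea::calcGseaStat(setNames(sig$scores, sig$genes),
                                  selectedStats = sort(idx), gseaParam = 1)
      expect_equal(enrichment_score(sig, set), want, tolerance = 1e-8)
    }
  })
})

test_that("connectivity score is -1 for perfect reversal, +1 for mimicry, 0 for same-sign enrichment", {
  universe <- sprintf("T%04d", 1:1000)
  dis <- disease_signature("ds1", up = universe[1:25], down = universe[26:50])

  reverser <- block_signature("rev", universe, top = dis$down,
                              bottom = dis$up, seed = 81)
  expect_lt(connectivity_score(reverser, dis), -0.9)

  mimic <- block_signature("mim", universe, top = dis$up,
                           bottom = dis$down, seed = 82)
  expect_gt(connectivity_score(mimic, dis), 0.9)

  # both sets at the top: same-sign enrichment scores -> 0 by convention
  same <- block_signature("same", universe, top = c(dis$up, dis$down),
                          seed = 83)
  expect_identical(connectivity_score(same, dis), 0)

  # unusable pair: disease sets absent from the ranking
  dis2 <- disease_signature("ds2", up = "absent1", down = "absent2")
  expect_error(connectivity_score(reverser, dis2), "intersect")
})

test_that("reversing the drug ranking flips the connectivity sign", {
  universe <- sprintf("T%04d", 1:400)
  dis <- disease_signature("ds", up = universe[1:15], down = universe[16:30])
  withr::with_seed(91, {
    for (i in 1:10) {
      scores <- setNames(rnorm(400), sample(universe))
      fwd <- drug_signature("d", scores)
      rev <- drug_signature("d", -scores)
      c_f <- connectivity_score(fwd, dis)
      c_r <- connectivity_score(rev, dis)
      # ES extrema are sign-flipped under ranking reversal, so a non-zero
      # WTCS flips sign (zero stays zero)
      expect_equal(c_r, -c_f, tolerance = 1e-6)
    }
  })
})

test_that("the integer reversal score counts strictly negative datasets and NA means no profile", {
  s <- gsea_score("d", c(-0.5, -0.1, 0.2), n_datasets = 3)
  expect_identical(s$score, 2L)
  s <- gsea_score("d", c(-0.5, -0.1, -0.2), n_datasets = 3)
  expect_identical(s$score, 3L)                   # the maximum at N = 3
  expect_identical(gsea_score("d", c(0, 0.3, 0.4), 3)$score, 0L)  # 0 not negative
  expect_true(is.na(gsea_score("d", NULL, 3)$score))
  expect_identical(gsea_score("d", c(-1, NA, NA), 3)$score, 1L)

  # invariant to dataset ordering, bounded by 0..N
  withr::with_seed(95, {
    for (i in 1:20) {
      conn <- runif(4, -1, 1)
      a <- gsea_score("d", conn, 4)$score
      b <- gsea_score("d", sample(conn), 4)$score
      expect_identical(a, b)
      expect_gte(a, 0L); expect_lte(a, 4L)
    }
  })
})

test_that("score_signatures aggregates a library over datasets with NA for absent drugs", {
  universe <- sprintf("T%04d", 1:500)
  ds1 <- disease_signature("ds1", up = universe[1:10], down = universe[11:20])
  ds2 <- disease_signature("ds2", up = universe[21:30], down = universe[31:40])
  lib <- list(
    rev = block_signature("rev", universe, top = c(ds1$down, ds2$down),
                          bottom = c(ds1$up, ds2$up), seed = 101))
  out <- score_signatures(lib, list(ds1, ds2), drug_ids = c("rev", "ghost"))
  expect_identical(out$gsea[out$drug_id == "rev"], 2L)
  expect_true(is.na(out$gsea[out$drug_id == "ghost"]))
  expect_true(all(out$n_datasets == 2L))
})

test_that("drug signature library round-trips through TSV and GMT formats", {
  universe <- sprintf("T%04d", 1:50)
  lib <- list(
    DBa = block_signature("DBa", universe, top = universe[1:5],
                          bottom = universe[6:10], seed = 111),
    DBb = block_signature("DBb", universe, top = universe[11:12], seed = 112))
  f <- tempfile()
  write_drug_signatures(lib, f)
  back <- read_drug_signatures(f)
  expect_setequal(names(back), names(lib))
  expect_identical(back$DBa$genes, lib$DBa$genes)
  expect_equal(back$DBa$scores, lib$DBa$scores)

  fg <- tempfile()
  writeLines(c(paste(c("DBc_UP", "up genes", universe[1:3]), collapse = "\t"),
               paste(c("DBc_DN", "down genes", universe[4:6]), collapse = "\t")),
             fg)
  gl <- read_drug_signatures_gmt(fg)
  expect_identical(names(gl), "DBc")
  expect_setequal(gl$DBc$genes[1:3], universe[1:3])
  expect_equal(unname(gl$DBc$scores), c(1, 1, 1, -1, -1, -1))
})
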