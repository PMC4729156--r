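test_that("annotation generation is a pure function of the parameters", {
  p <- sim_params(n_genes = 50, seed = 1)
  a1 <- generate_annotation(p)
  a2 <- generate_annotation(p)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
})

test_that("the human-like regime has more isoforms per gene than the fly-like", {
  mean_iso <- function(regime, seed) {
    p <- sim_params(n_genes = 25, regime = regime, seed = seed)
    gt <- gene_table(generate_annotation(p))
    mean(gt$n_transcripts)
  }
  seeds <- 1:20
  fly <- vapply(seeds, function(s) mean_iso("fruitfly_like", s), 1)
  hum <- vapply(seeds, function(s) mean_iso("human_like", s), 1)
  expect_gt(mean(hum), mean(fly))
  # and the fly-like regime has longer exons
  p1 <- sim_params(n_genes = 25, regime = "fruitfly_like", seed = 3)
  p2 <- sim_params(n_genes = 25, regime = "human_like", seed = 3)
  a1 <- generate_annotation(p1); a2 <- generate_annotation(p2)
  expect_gt(median(a1$end - a1$start), median(a2$end - a2$start))
})

test_that("no two isoforms of a gene share the same exon structure", {
  p <- sim_params(n_genes = 40, regime = "human_like", seed = 8)
  ann <- generate_annotation(p)
  sig <- tapply(paste(ann$start, ann$end), ann$transcript_id,
                paste, collapse = ";")
  gene_of <- tapply(ann$gene_id, ann$transcript_id, `[`, 1)
  dup <- tapply(sig, gene_of, anyDuplicated)
  expect_true(all(dup == 0))
})

test_that("the mean-dispersion relationship evaluates as a0 + a1/mu", {
  expect_equal(dispersion_from_mean(300, c(a0 = 0.01, a1 = 3)), 0.02)
  expect_equal(dispersion_from_mean(c(10, 100), c(0.05, 0)),
               c(0.05, 0.05))
  mu <- c(10, 100, 1000)
  expect_true(all(diff(dispersion_from_mean(mu, c(0.01, 3))) < 0))
  expect_error(dispersion_from_mean(0, c(0.01, 3)), "positive")
})

test_that("effective length floors at one and is the identity at unit fragments", {
  expect_equal(effective_length(1000, 250), 751)
  expect_equal(effective_length(100, 250), 1)
  expect_equal(effective_length(777, 1), 777)
})

test_that("expression model scales means to the on-target library size", {
  p <- sim_params(n_genes = 60, library_size = 1e5, seed = 4)
  ann <- generate_annotation(p)
  model <- build_expression_model(ann, p)
  expect_equal(sum(model$genes$mu), 1e5 * 0.95, tolerance = 1e-3)
  frac_sum <- tapply(model$isoforms$pi_1, model$isoforms$gene_id, sum)
  expect_equal(as.numeric(frac_sum), rep(1, nrow(model$genes)),
               tolerance = 1e-12)
  # fractions sorted decreasing within genes, condition 2 initialized equal
  expect_identical(model$isoforms$pi_1, model$isoforms$pi_2)
  model2 <- build_expression_model(ann, p)
  expect_identical(model, model2)
})

fake_model <- function(pi_list, mu, lens = NULL) {
  gid <- sprintf("g%d", seq_along(pi_list))
  iso <- do.call(rbind, lapply(seq_along(pi_list), function(i)
    data.frame(transcript_id = sprintf("g%d_t%d", i,
                                       seq_along(pi_list[[i]])),
               gene_id = gid[i], length = 1000,
               eff_len = 751, pi_1 = pi_list[[i]],
               pi_2 = pi_list[[i]], stringsAsFactors = FALSE)))
  structure(list(
    genes = data.frame(gene_id = gid, mu = mu,
                       phi = 0.05, eff_len = 751,
                       stringsAsFactors = FALSE),
    isoforms = iso), class = "dtu_expression_model")
}

test_that("DTU eligibility needs two expressed isoforms and enough counts", {
  model <- fake_model(list(c(0.6, 0.3, 0.1), c(0.95, 0.05), c(0.6, 0.4)),
                      mu = c(600, 1e4, 499))
  p <- sim_params(n_genes = 3, n_dtu = 1, seed = 2)
  truth <- select_dtu_genes(model, p)
  expect_equal(truth$gene_id[truth$dtu_status], "g1")
  expect_equal(truth$n_isoforms, c(3L, 2L, 2L))
  expect_equal(truth$dominance_diff, c(0.3, 0.9, 0.2))
  p2 <- sim_params(n_genes = 3, n_dtu = 2, seed = 2)
  expect_error(select_dtu_genes(model, p2), "1 of 3")
})

test_that("the swap exchanges the top-two fractions in condition 2 only", {
  model <- fake_model(list(c(0.7, 0.2, 0.1), c(0.5, 0.5)),
                      mu = c(1000, 1000))
  truth <- data.frame(gene_id = c("g1", "g2"),
                      dtu_status = c(TRUE, FALSE),
                      swapped_1 = c("g1_t1", NA),
                      swapped_2 = c("g1_t2", NA),
                      stringsAsFactors = FALSE)
  out <- apply_dtu_swap(model, truth)
  expect_equal(out$isoforms$pi_2[out$isoforms$gene_id == "g1"],
               c(0.2, 0.7, 0.1))
  expect_equal(out$isoforms$pi_1, model$isoforms$pi_1)
  expect_equal(out$isoforms$pi_2[out$isoforms$gene_id == "g2"],
               c(0.5, 0.5))
  # tied top two: the swap is a no-op
  tied <- fake_model(list(c(0.4, 0.4, 0.2)), mu = 1000)
  tr <- data.frame(gene_id = "g1", dtu_status = TRUE,
                   swapped_1 = "g1_t1", swapped_2 = "g1_t2")
  out2 <- apply_dtu_swap(tied, tr)
  expect_equal(out2$isoforms$pi_2, tied$isoforms$pi_1)
})

test_that("sample expression reproduces the NB moments and the TPM identity", {
  p <- sim_params(n_genes = 1, seed = 1)
  model <- fake_model(rep(list(1), 2000), mu = rep(100, 2000))
  model$genes$phi <- 0.1
  se <- simulate_sample_expression(model, 1, "s1", p, seed = 99)
  k <- se$genes$count
  expect_equal(mean(k), 100, tolerance = 0.05)
  expect_equal(var(k), 100 + 0.1 * 100^2, tolerance = 0.15)
  expect_equal(sum(se$isoforms$tpm), 1e6, tolerance = 1e-9)
  # fractions per gene sum to one
  fs <- tapply(se$isoforms$fraction, se$isoforms$gene_id, sum)
  expect_equal(as.numeric(fs), rep(1, 2000), tolerance = 1e-12)
})

test_that("Dirichlet fractions concentrate around pi as the scale grows", {
  p_small <- sim_params(n_genes = 1, dirichlet_scale = 100, seed = 1)
  p_big <- sim_params(n_genes = 1, dirichlet_scale = 1e6, seed = 1)
  model <- fake_model(list(c(0.5, 0.3, 0.2)), mu = 1000)
  se <- simulate_sample_expression(model, 1, "s", p_big, seed = 5)
  expect_lt(max(abs(se$isoforms$fraction - c(0.5, 0.3, 0.2))), 0.01)
  # zero-fraction isoforms stay at zero
  model0 <- fake_model(list(c(0.7, 0.3, 0.0)), mu = 1000)
  se0 <- simulate_sample_expression(model0, 1, "s", p_small, seed = 6)
  expect_equal(se0$isoforms$fraction[3], 0)
  expect_equal(sum(se0$isoforms$fraction), 1)
})

test_that("transcript-to-genome projection splits reads at junctions", {
  # single exon [0,1000): fragment at transcript start, length 250
  b1 <- dtubench:::project_tx_range(0L, 1000L, 0, 101)
  expect_equal(b1[, c("start", "end")],
               data.frame(start = 0L, end = 101L))
  b2 <- dtubench:::project_tx_range(0L, 1000L, 149, 250)
  expect_equal(b2[, c("start", "end")],
               data.frame(start = 149L, end = 250L))
  # junction [0,100)+[200,300), read of 101 bases at transcript pos 50
  b3 <- dtubench:::project_tx_range(c(0L, 200L), c(100L, 100L), 50, 151)
  expect_equal(b3$start, c(50L, 200L))
  expect_equal(b3$end, c(100L, 251L))
})

test_that("fragments respect transcript structure and the background share", {
  ann <- dtu_annotation(data.frame(
    gene_id = "g1", transcript_id = c("t1", "t1"), chrom = "chrS",
    start = c(0L, 2000L), end = c(1000L, 3000L), strand = "+"))
  p <- sim_params(n_genes = 1, library_size = 1e4, seed = 2)
  model <- fake_model(list(1), mu = 9500)
  model$isoforms$transcript_id <- "t1"
  model$isoforms$gene_id <- "g1"
  model$genes$gene_id <- "g1"
  se <- simulate_sample_expression(model, 1, "s1", p, seed = 3)
  fr <- simulate_fragments(ann, se, p, seed = 4)
  expect_equal(sum(fr$fragments$origin == "background"), 500L)
  expect_equal(nrow(fr$fragments), 10000L)
  # every non-background block lies within an exon
  tx_blocks <- fr$blocks[fr$fragments$origin[fr$blocks$frag] != "background", ]
  in_exon <- (tx_blocks$start >= 0 & tx_blocks$end <= 1000) |
    (tx_blocks$start >= 2000 & tx_blocks$end <= 3000)
  expect_true(all(in_exon))
  # each mate covers exactly read_length bases
  mate_len <- tapply(tx_blocks$end - tx_blocks$start,
                     paste(tx_blocks$frag, tx_blocks$mate), sum)
  expect_true(all(mate_len == 101))
})

test_that("fragment starts are uniform along a single-exon transcript", {
  ann <- dtu_annotation(data.frame(
    gene_id = "g1", transcript_id = "t1", chrom = "chrS",
    start = 0L, end = 5000L, strand = "+"))
  p <- sim_params(n_genes = 1, library_size = 1e4,
                  background_fraction = 0, fragment_length_sd = 0,
                  seed = 2)
  model <- fake_model(list(1), mu = 1e4)
  model$isoforms$transcript_id <- "t1"; model$isoforms$gene_id <- "g1"
  model$genes$gene_id <- "g1"
  se <- simulate_sample_expression(model, 1, "s1", p, seed = 3)
  fr <- simulate_fragments(ann, se, p, seed = 4)
  starts <- fr$blocks$start[fr$blocks$mate == 1]
  ks <- suppressWarnings(ks.test(starts, "punif", 0, 5000 - 250))
  expect_gt(ks$p.value, 0.01)
})

test_that("expected gene output is identical across conditions (no DE)", {
  p <- sim_params(n_genes = 30, library_size = 3e4, n_dtu = 6, seed = 6)
  ann <- generate_annotation(p)
  model <- build_expression_model(ann, p)
  truth <- select_dtu_genes(model, p)
  model <- apply_dtu_swap(model, truth)
  diffs <- vapply(1:50, function(i) {
    s1 <- simulate_sample_expression(model, 1, "a", p, seed = 1000 + i)
    s2 <- simulate_sample_expression(model, 2, "b", p, seed = 2000 + i)
    sum(s1$genes$count) - sum(s2$genes$count)
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-9)
})

test_that("truth tables round-trip through TSV with extra columns intact", {
  truth <- data.frame(gene_id = c("g1", "g2"),
                      dtu_status = c(TRUE, FALSE),
                      swapped_1 = c("t1", NA), swapped_2 = c("t2", NA),
                      n_isoforms = c(3L, 1L),
                      dominance_diff = c(0.4, 1),
                      expected_count = c(600.5, 20),
                      note = c("x", "y"), stringsAsFactors = FALSE)
  f <- tempfile()
  write_truth(truth, f)
  back <- read_truth(f)
  expect_equal(as.data.frame(back), truth, ignore_attr = TRUE)
  empty <- truth[0, ]
  write_truth(empty, f)
  expect_equal(nrow(read_truth(f)), 0L)
})

test_that("fragments round-trip through BED12", {
  frags <- make_fragments(list(
    list(mate1 = cbind(50L, 151L), mate2 = cbind(c(180L, 300L),
                                                 c(200L, 381L))),
    list(mate1 = cbind(0L, 101L), mate2 = cbind(149L, 250L))),
    sample_ids = "s1", origins = c("tA", "background"))
  f <- tempfile(fileext = ".bed")
  write_fragments_bed12(frags, f)
  back <- read_fragments_bed12(f, sample_id = "s1")
  expect_equal(back$fragments$origin, frags$fragments$origin)
  expect_equal(back$blocks[c("frag", "mate", "start", "end")],
               frags$blocks[c("frag", "mate", "start", "end")])
})
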