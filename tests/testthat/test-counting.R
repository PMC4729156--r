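flat_two_bin_set <- function() {
  flatten(dtu_annotation(data.frame(
    gene_id = "g1", transcript_id = c("t1", "t1", "t2"),
    chrom = "chrS", start = c(0L, 200L, 0L), end = c(100L, 300L, 100L),
    strand = "+")), "exclude_same_strand")
}

test_that("fragments are assigned to every overlapped bin, once each", {
  bs <- flat_two_bin_set()  # bins [0,100) and [200,300)
  frags <- make_fragments(list(
    # spans both bins -> +1 to each
    list(mate1 = cbind(50L, 100L), mate2 = cbind(200L, 260L)),
    # both mates in the same bin -> one count only
    list(mate1 = cbind(0L, 60L), mate2 = cbind(30L, 90L)),
    # overlaps nothing
    list(mate1 = cbind(150L, 180L), mate2 = cbind(150L, 180L))))
  cm <- count_flat_or_exon(frags, bs)
  expect_equal(unname(cm$counts[, "s1"]), c(2L, 1L))
  expect_equal(sum(cm$counts), 3)
})

test_that("overlap counting matches the brute-force oracle on random toys", {
  set.seed(404)
  for (i in 1:5) {
    ann <- random_toy_annotation(2)
    bs <- flatten(ann, "exclude_same_strand")
    span <- range(c(ann$start, ann$end))
    frag_list <- lapply(1:40, function(f) {
      s <- sample(seq(span[1] - 100, span[2] + 100), 1)
      l <- sample(60:250, 1)
      list(mate1 = cbind(s, s + 50L),
           mate2 = cbind(s + l - 50L, s + l))
    })
    frags <- make_fragments(frag_list,
                            sample_ids = rep(c("s1", "s2"), 20))
    cm <- count_flat_or_exon(frags, bs)
    expect_equal(cm$counts, oracle_overlap_counts(frags, bs))
  }
})

test_that("counting is linear: duplicated fragments double every entry", {
  bs <- flat_two_bin_set()
  frag_list <- list(
    list(mate1 = cbind(10L, 80L), mate2 = cbind(220L, 280L)),
    list(mate1 = cbind(0L, 50L), mate2 = cbind(40L, 95L)))
  one <- count_flat_or_exon(make_fragments(frag_list), bs)
  two <- count_flat_or_exon(make_fragments(c(frag_list, frag_list)), bs)
  expect_equal(two$counts, 2L * one$counts)
})

test_that("junction counting requires an exact boundary match", {
  ann <- dtu_annotation(data.frame(
    gene_id = "g1", transcript_id = c("t1", "t1"), chrom = "chrS",
    start = c(0L, 200L), end = c(100L, 300L), strand = "+"))
  js <- junction_set(ann)  # junction (100, 200)
  frags <- make_fragments(list(
    list(mate1 = cbind(c(50L, 200L), c(100L, 251L)),  # spans exactly
         mate2 = cbind(230L, 300L)),
    list(mate1 = cbind(10L, 90L), mate2 = cbind(20L, 95L)),  # within exon
    list(mate1 = cbind(c(50L, 201L), c(99L, 251L)),  # off by one
         mate2 = cbind(230L, 300L))))
  cm <- count_junctions(frags, js)
  expect_equal(unname(cm$counts[, "s1"]), 1L)
})

test_that("junction support implies overlap of both flanking flat bins", {
  set.seed(17)
  p <- sim_params(n_genes = 8, library_size = 4000, seed = 17)
  sim <- simulate_experiment(p)
  frags <- dtubench:::combine_fragments(sim$fragments)
  fl <- flatten(sim$annotation, "exclude_same_strand")
  js <- junction_set(sim$annotation)
  cj <- count_junctions(frags, js)
  cf <- count_flat_or_exon(frags, fl)
  # for each junction, the flat bins touching donor/acceptor must hold
  # at least as many fragments
  for (k in seq_len(nrow(js$bins))) {
    d <- js$bins$donor[k]; a <- js$bins$acceptor[k]
    jcount <- cj$counts[js$bins$bin_id[k], ]
    ivs <- fl$intervals
    left <- ivs$bin_id[ivs$end == d]
    right <- ivs$bin_id[ivs$start == a]
    if (length(left))
      expect_true(all(cf$counts[left[1], ] >= jcount))
    if (length(right))
      expect_true(all(cf$counts[right[1], ] >= jcount))
  }
})

shared_region_ann <- function() {
  # t1: [0,100)+[200,300); t2: [0,100)+[400,500): first exon shared
  dtu_annotation(data.frame(
    gene_id = "g1", transcript_id = c("t1", "t1", "t2", "t2"),
    chrom = "chrS", start = c(0L, 200L, 0L, 400L),
    end = c(100L, 300L, 100L, 500L), strand = "+"))
}

test_that("equivalence classes reflect transcript compatibility", {
  ann <- shared_region_ann()
  frags <- make_fragments(list(
    # unique to t1 (second exon)
    list(mate1 = cbind(210L, 260L), mate2 = cbind(230L, 290L)),
    # shared first exon -> {t1, t2}
    list(mate1 = cbind(0L, 60L), mate2 = cbind(30L, 99L)),
    # spans t1's junction -> {t1}
    list(mate1 = cbind(c(60L, 200L), c(100L, 240L)),
         mate2 = cbind(220L, 280L)),
    # incompatible with both (intronic)
    list(mate1 = cbind(120L, 160L), mate2 = cbind(130L, 170L))))
  ecs <- build_equivalence_classes(frags, ann)
  keys <- vapply(ecs$transcripts, paste, "", collapse = ",")
  expect_setequal(keys, c("t1", "t1,t2"))
  expect_equal(sum(ecs$counts), 3L)
  expect_equal(unname(ecs$n_incompatible["s1"]), 1L)
  expect_equal(unname(ecs$counts[keys == "t1", "s1"]), 2L)
})

test_that("EM resolves trivial configurations exactly", {
  # all singleton classes: output equals the class counts
  ecs <- list(transcripts = list("t1", "t2"),
              counts = matrix(c(30L, 70L), 2, 1,
                              dimnames = list(NULL, "s1")))
  eff <- c(t1 = 500, t2 = 500)
  cm <- em_quantify(ecs, eff)
  expect_equal(unname(cm$counts[, 1]), c(30, 70), tolerance = 1e-6)
  # complete ambiguity with equal lengths splits evenly
  ecs2 <- list(transcripts = list(c("t1", "t2")),
               counts = matrix(100L, 1, 1, dimnames = list(NULL, "s1")))
  cm2 <- em_quantify(ecs2, eff)
  expect_equal(unname(cm2$counts[, 1]), c(50, 50), tolerance = 1e-6)
})

test_that("EM matches the grid-search ML oracle and increases likelihood", {
  set.seed(55)
  for (i in 1:8) {
    k <- sample(2:3, 1)
    eff <- setNames(sample(300:900, k), paste0("t", seq_len(k)))
    subsets <- list()
    for (j in seq_len(k)) subsets[[j]] <- j
    if (k == 2) subsets <- c(subsets, list(1:2))
    else subsets <- c(subsets, list(c(1, 2), c(2, 3), 1:3))
    pick <- sort(sample(seq_along(subsets),
                        sample(2:length(subsets), 1)))
    covered <- sort(unique(unlist(subsets[pick])))
    ec_tx <- lapply(subsets[pick], function(s) match(s, covered))
    eff_c <- eff[covered]
    cts <- sample(5:200, length(pick))
    ecs <- list(transcripts = lapply(ec_tx, function(s) names(eff_c)[s]),
                counts = matrix(as.integer(cts), length(cts), 1,
                                dimnames = list(NULL, "s1")))
    cm <- em_quantify(ecs, eff_c)
    want <- oracle_em_grid(ec_tx, cts, unname(eff_c))
    got <- setNames(rep(0, length(covered)), names(eff_c))
    got[rownames(cm$counts)] <- cm$counts[, 1]
    expect_lt(max(abs(unname(got) - want)), 0.01 * sum(cts) + 0.5)
    ll <- attr(cm, "loglik")
    expect_true(all(diff(ll) >= -1e-8))
  }
})

test_that("count matrices round-trip through TSV with their feature map", {
  bs <- flat_two_bin_set()
  frags <- make_fragments(list(
    list(mate1 = cbind(10L, 80L), mate2 = cbind(220L, 280L))),
    sample_ids = "s1")
  cm <- count_flat_or_exon(frags, bs)
  f <- tempfile(fileext = ".tsv")
  write_counts(cm, f)
  back <- read_counts(f)
  expect_equal(back$counts, cm$counts * 1.0)
  expect_equal(back$feature, cm$feature)
  expect_equal(back$bin_type, cm$bin_type)
})
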