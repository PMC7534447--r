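# Builds a contig with an exact GC fraction (length 100).
gc_contig <- function(gc) {
  n_gc <- round(100 * gc)
  paste0(strrep("G", ceiling(n_gc / 2)), strrep("C", floor(n_gc / 2)),
         strrep("A", ceiling((100 - n_gc) / 2)),
         strrep("T", floor((100 - n_gc) / 2)))
}

test_that("gc_fraction excludes N and ambiguity codes", {
  expect_equal(gc_fraction("GGCC"), 1.0)
  expect_equal(gc_fraction("ATNNAT"), 0.0)
  expect_equal(gc_fraction("ACGTacgt"), 0.5)
  expect_equal(gc_fraction("ACGTRYSW"), 0.5)  # ambiguity codes dropped
  expect_true(is.na(gc_fraction("NNNN")))
})

test_that("taxonomy keyword and rescue rules fire with correct attribution", {
  asm <- seq_set(c(keep_tax = gc_contig(0.31),
                   rescue_me = gc_contig(0.31),
                   mismatch = gc_contig(0.31)))
  hits <- data.frame(contig_id = c("keep_tax", "mismatch"),
                     description = c("Vespula vulgaris venom allergen",
                                     "Escherichia coli plasmid"))
  rep <- classify_contigs(asm, hits, rescue = c(rescue_me = 2))
  d <- setNames(rep$rule, rep$contig_id)
  expect_identical(d[["keep_tax"]], "taxonomy_keyword")
  expect_identical(d[["rescue_me"]], "orthogroup_rescue")
  expect_identical(d[["mismatch"]], "taxonomy_mismatch")
  expect_identical(rep$verdict[rep$contig_id == "mismatch"], "discard")
})

test_that("keyword matching is case-insensitive substring by default", {
  asm <- seq_set(c(c1 = gc_contig(0.31), c2 = gc_contig(0.31)))
  hits <- data.frame(contig_id = c("c1", "c2"),
                     description = c("common WASP protein", "waspish thing"))
  rep <- classify_contigs(asm, hits)
  expect_true(all(rep$rule == "taxonomy_keyword"))
  # whole-word mode rejects the embedded match
  rep_w <- classify_contigs(asm, hits, whole_word = TRUE)
  d <- setNames(rep_w$rule, rep_w$contig_id)
  expect_identical(d[["c1"]], "taxonomy_keyword")
  expect_identical(d[["c2"]], "taxonomy_mismatch")
})

test_that("GC band uses the hand-computed mean and sample SD of rule-1/2 keepers", {
  keepers <- c(rep(0.30, 5), rep(0.32, 5))
  seqs <- vapply(keepers, gc_contig, character(1))
  names(seqs) <- sprintf("k%02d", 1:10)
  seqs <- c(seqs, cand_hi = gc_contig(0.55), cand_in = gc_contig(0.31))
  asm <- seq_set(seqs)
  hits <- data.frame(contig_id = sprintf("k%02d", 1:10),
                     description = "Polistes dominula scaffold")
  rep <- classify_contigs(asm, hits)
  expect_equal(attr(rep, "gc_mean"), 0.31)
  expect_equal(attr(rep, "gc_sd"), sd(keepers))
  d <- setNames(rep$rule, rep$contig_id)
  expect_identical(d[["cand_hi"]], "gc_outside_band")
  expect_identical(d[["cand_in"]], "gc_within_band")
  expect_identical(rep$verdict[rep$contig_id == "cand_hi"], "discard")
})

test_that("band bounds are inclusive and the band is single-pass", {
  keepers <- c(rep(0.30, 5), rep(0.32, 5))
  band_hi <- 0.31 + 2 * sd(keepers)             # ~0.33108
  seqs <- vapply(keepers, gc_contig, character(1))
  names(seqs) <- sprintf("k%02d", 1:10)
  # 0.33 is inside; length-1000 contig at exact upper bound impossible at
  # resolution 0.001, so check the inclusive side with an in-band value
  seqs <- c(seqs, edge = gc_contig(0.33))
  asm <- seq_set(seqs)
  hits <- data.frame(contig_id = sprintf("k%02d", 1:10),
                     description = "wasp contig")
  rep <- classify_contigs(asm, hits)
  expect_identical(rep$verdict[rep$contig_id == "edge"], "keep")
  expect_lt(0.33, band_hi)
})

test_that("rule precedence is strict: keyword hit never reaches rules 2-3", {
  # a keyword contig with wild GC is still kept
  asm <- seq_set(c(wild = gc_contig(0.90), k1 = gc_contig(0.31),
                   k2 = gc_contig(0.30)))
  hits <- data.frame(contig_id = c("wild", "k1", "k2"),
                     description = "Vespula sp. scaffold")
  rep <- classify_contigs(asm, hits)
  expect_identical(setNames(rep$rule, rep$contig_id)[["wild"]],
                   "taxonomy_keyword")
})

test_that("degenerate cases: no keepers errors, undefined GC discards", {
  asm <- seq_set(c(c1 = gc_contig(0.31)))
  expect_error(classify_contigs(asm, NULL, NULL), "Relax keep_keywords")
  asm2 <- seq_set(c(k1 = gc_contig(0.30), k2 = gc_contig(0.32),
                    allN = "NNNNNNNN"))
  hits <- data.frame(contig_id = c("k1", "k2"), description = "wasp")
  expect_warning(rep <- classify_contigs(asm2, hits), "undefined GC")
  expect_identical(rep$verdict[rep$contig_id == "allN"], "discard")
  expect_identical(rep$rule[rep$contig_id == "allN"], "gc_outside_band")
})

test_that("classification is deterministic and order-independent", {
  sim <- simulate_assembly(n_host_contigs = 15, n_contaminant_contigs = 5,
                           seed = 99)
  r1 <- classify_contigs(sim$assembly, sim$taxonomy_hits, sim$rescue)
  r2 <- classify_contigs(sim$assembly, sim$taxonomy_hits[sample(nrow(sim$taxonomy_hits)), ],
                         sim$rescue)
  expect_identical(r1$verdict, r2$verdict)
  expect_identical(r1$rule, r2$rule)
})

test_that("planted contaminants are discarded with perfect precision and recall", {
  for (seed in 1:5) {
    sim <- simulate_assembly(seed = seed)   # 50 host + 10 contaminant defaults
    rep <- classify_contigs(sim$assembly, sim$taxonomy_hits, sim$rescue)
    truth <- setNames(sim$truth$class, sim$truth$contig_id)
    discarded <- rep$contig_id[rep$verdict == "discard"]
    expect_setequal(discarded,
                    sim$truth$contig_id[sim$truth$class == "contaminant"])
    # rule attribution consistent with planted evidence
    with_hit <- sim$truth$contig_id[sim$truth$has_hit]
    expect_true(all(rep$rule[rep$contig_id %in% with_hit] %in%
                      c("taxonomy_keyword", "taxonomy_mismatch")))
    rescued <- sim$truth$contig_id[!sim$truth$has_hit &
                                     sim$truth$rescued_genes > 0]
    expect_true(all(rep$rule[rep$contig_id %in% rescued] ==
                      "orthogroup_rescue"))
  }
})

test_that("apply_curation keeps exactly the keep-verdict contigs in order", {
  sim <- simulate_assembly(n_host_contigs = 10, n_contaminant_contigs = 4,
                           seed = 2)
  rep <- classify_contigs(sim$assembly, sim$taxonomy_hits, sim$rescue)
  out <- apply_curation(sim$assembly, rep)
  expect_identical(names(out),
                   intersect(names(sim$assembly),
                             rep$contig_id[rep$verdict == "keep"]))
  all_keep <- rep; all_keep$verdict <- "keep"
  expect_identical(unclass(apply_curation(sim$assembly, all_keep)),
                   unclass(sim$assembly))
  all_drop <- rep; all_drop$verdict <- "discard"
  expect_error(apply_curation(sim$assembly, all_drop), "empty assembly")
})

test_that("assign_names ranks by length with stable ties and four-digit scaffolds", {
  lens <- c(300, 100, 200, 100, 50, 40, 30)
  seqs <- vapply(lens, function(L) strrep("A", L), character(1))
  names(seqs) <- paste0("c", seq_along(lens))
  map <- assign_names(seq_set(seqs), n_chromosomes = 5)
  expect_identical(map$new_id,
                   c("Chr1", "Chr2", "Chr3", "Chr4", "Chr5",
                     "Scaffold0001", "Scaffold0002"))
  # equal-length tie: earlier input record gets the smaller rank
  expect_identical(map$old_id[map$new_id == "Chr3"], "c2")
  expect_identical(map$old_id[map$new_id == "Chr4"], "c4")
})

test_that("assign_names matches a brute-force sort oracle on random lengths", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(2:30, 1)
    lens <- sample(10:500, n, replace = TRUE)
    seqs <- vapply(lens, function(L) strrep("C", L), character(1))
    names(seqs) <- sprintf("s%02d", seq_len(n))
    map <- assign_names(seq_set(seqs), n_chromosomes = sample(0:n, 1))
    oracle <- names(seqs)[order(-lens, seq_len(n))]
    expect_identical(map$old_id, oracle)
    expect_identical(map$length,
                     unname(setNames(lens, names(seqs))[map$old_id]))
  }
})

test_that("fewer records than n_chromosomes warns and names all as chromosomes", {
  asm <- seq_set(c(a = "ACGTACGT", b = "ACG"))
  expect_warning(map <- assign_names(asm, n_chromosomes = 25), "fewer records")
  expect_identical(map$new_id, c("Chr1", "Chr2"))
  renamed <- apply_naming(asm, map)
  expect_identical(names(renamed), c("Chr1", "Chr2"))
})
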