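test_that("species_summary tallies representation and specificity by hand", {
  counts <- matrix(c(1, 1,
                     2, 0),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("A", "B"), c("sp1", "sp2")))
  s <- species_summary(orthogroup_table(counts))
  r1 <- s[s$species == "sp1", ]
  expect_equal(r1$orthogroups_represented, 2)
  expect_equal(r1$species_specific_orthogroups, 1)   # B
  expect_equal(r1$genes_in_specific, 2)
  r2 <- s[s$species == "sp2", ]
  expect_equal(r2$orthogroups_represented, 1)
  expect_equal(r2$species_specific_orthogroups, 0)
  # without unassigned counts, gene-total percentages are NA
  expect_true(all(is.na(s$gene_total)))
  # with unassigned counts, Table-2-style percentages appear
  s2 <- species_summary(orthogroup_table(counts,
                                         unassigned = c(sp1 = 7, sp2 = 9)))
  expect_equal(s2$gene_total, c(10, 10))
  expect_equal(s2[s2$species == "sp1", "genes_in_specific_pct"], 20)
})

test_that("species-specific orthogroups are disjoint across species", {
  sim <- simulate_orthogroup_table(n_species = 5, n_core = 40,
                                   n_accessory = 60, n_specific = 8,
                                   seed = 4)
  s <- species_summary(sim$table)
  expect_lte(sum(s$species_specific_orthogroups), nrow(sim$table$counts))
})

test_that("shared_orthogroups counts intersections and is monotone", {
  counts <- matrix(c(1, 1, 0,
                     1, 0, 1,
                     1, 1, 1),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), c("sp1", "sp2", "sp3")))
  tab <- orthogroup_table(counts)
  expect_equal(shared_orthogroups(tab, c("sp1", "sp2")), 2)   # A, C
  expect_equal(shared_orthogroups(tab, c("sp1", "sp2", "sp3")), 1)
  expect_lte(shared_orthogroups(tab, c("sp1", "sp2", "sp3")),
             shared_orthogroups(tab, c("sp1", "sp2")))
  expect_error(shared_orthogroups(tab, "sp1"), "at least 2")
  expect_error(shared_orthogroups(tab, c("sp1", "nope")), "unknown")
})

test_that("venn3_counts enumerates the 7 regions correctly", {
  counts <- matrix(c(1, 1, 0,
                     1, 0, 1,
                     1, 1, 1,
                     0, 0, 1),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(c("A", "B", "C", "D"),
                                   c("s1", "s2", "s3")))
  tab <- orthogroup_table(counts)
  v <- venn3_counts(tab, c("s1", "s2", "s3"))
  expect_equal(unname(v[["s1&s2"]]), 1)        # A
  expect_equal(unname(v[["s1&s3"]]), 1)        # B
  expect_equal(unname(v[["s1&s2&s3"]]), 1)     # C
  expect_equal(unname(v[["s3"]]), 1)           # D
  expect_equal(sum(v), 4)
  # region sums equal the 3-species pan
  curve <- pan_core_curve(tab, cap = 10, seed = 1)
  expect_equal(sum(v), max(curve$pan[curve$k == 3]))
  expect_error(venn3_counts(tab, c("s1", "s1", "s2")), "distinct")
})

test_that("all-shared table puts everything in the triple region", {
  counts <- matrix(1, 3, 3, dimnames = list(paste0("OG", 1:3),
                                            c("x", "y", "z")))
  v <- venn3_counts(orthogroup_table(counts), c("x", "y", "z"))
  expect_equal(unname(v[["x&y&z"]]), 3)
  expect_equal(sum(v), 3)
})

test_that("pan_core_curve matches the exhaustive worked example", {
  tab <- worked_og_table()   # A=[1,1,1], B=[1,1,0], C=[0,0,1]
  curve <- pan_core_curve(tab, cap = 1000, seed = 1)
  expect_true(all(curve$exhaustive))
  k3 <- curve[curve$k == 3, ]
  expect_equal(k3$core, 1); expect_equal(k3$pan, 3)
  k2 <- curve[curve$k == 2, ]
  pick <- function(members) k2[k2$members == members, c("core", "pan")]
  expect_equal(unlist(pick("sp1,sp2")), c(core = 2, pan = 2))
  expect_equal(unlist(pick("sp1,sp3")), c(core = 1, pan = 3))
  expect_equal(unlist(pick("sp2,sp3")), c(core = 1, pan = 3))
  # k = 1: core = pan per singleton
  k1 <- curve[curve$k == 1, ]
  expect_equal(k1$core, k1$pan)
})

test_that("core-only tables give flat core = pan curves", {
  sim <- simulate_orthogroup_table(n_species = 4, n_core = 25,
                                   n_accessory = 0, n_specific = 0, seed = 8)
  curve <- pan_core_curve(sim$table, cap = 100, seed = 2)
  expect_true(all(curve$core == 25))
  expect_true(all(curve$pan == 25))
})

test_that("exhaustive mean core is non-increasing and mean pan non-decreasing", {
  for (seed in 1:4) {
    sim <- simulate_orthogroup_table(n_species = 6, n_core = 30,
                                     n_accessory = 50, n_specific = 5,
                                     seed = seed)
    agg <- pan_core_means(pan_core_curve(sim$table, cap = 100, seed = seed))
    expect_true(all(diff(agg$mean_core) <= 1e-9))
    expect_true(all(diff(agg$mean_pan) >= -1e-9))
    n <- length(sim$table$species)
    expect_equal(agg$mean_core[n], shared_orthogroups(sim$table,
                                                      sim$table$species))
    expect_equal(agg$mean_pan[n], nrow(sim$table$counts))
  }
})

test_that("sampling is reproducible and capped subsets are distinct", {
  sim <- simulate_orthogroup_table(n_species = 10, n_core = 20,
                                   n_accessory = 40, n_specific = 2, seed = 5)
  c1 <- pan_core_curve(sim$table, cap = 50, seed = 42)
  c2 <- pan_core_curve(sim$table, cap = 50, seed = 42)
  expect_identical(c1, c2)
  k5 <- c1[c1$k == 5, ]
  expect_false(all(k5$exhaustive))             # C(10,5) = 252 > 50
  expect_identical(nrow(k5), 50L)
  expect_identical(anyDuplicated(k5$members), 0L)
  c3 <- pan_core_curve(sim$table, cap = 50, seed = 43)
  expect_false(identical(k5$members, c3[c3$k == 5, "members"]))
})

test_that("sampled means agree with exhaustive means within 3 SEs", {
  sim <- simulate_orthogroup_table(n_species = 10, n_core = 30,
                                   n_accessory = 80, n_specific = 3, seed = 6)
  exh <- pan_core_curve(sim$table, cap = 100000, seed = 1)
  smp <- pan_core_curve(sim$table, cap = 100, seed = 9)
  for (k in c(4, 5, 6)) {
    ce <- exh$core[exh$k == k]
    cs <- smp$core[smp$k == k]
    se <- sd(ce) / sqrt(length(cs))
    expect_lt(abs(mean(cs) - mean(ce)), 3 * se + 1e-12)
  }
})

test_that("pan_closure reports last-step growth", {
  tab <- worked_og_table()
  curve <- pan_core_curve(tab, cap = 100, seed = 1)
  cl <- pan_closure(curve, threshold = 1)
  expect_equal(cl$final_pan, 3)
  agg <- pan_core_means(curve)
  expect_equal(cl$last_step_growth, agg$mean_pan[3] - agg$mean_pan[2])
})
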