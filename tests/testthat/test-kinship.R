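test_that("kinship and inbreeding reproduce the analytic identities", {
  ped <- parent_offspring_ped()
  expect_identical(inbreeding(ped, "X")$f, 0.25)       # parent-offspring mating
  expect_identical(inbreeding(halfsib_ped(), "X")$f, 0.125)
  gp <- grandmother_ped()
  expect_identical(kinship(gp, "GM", "G")$kinship, 0.125)
  expect_identical(kinship(ped, "A", "B")$kinship, 0)  # two founders
  expect_identical(kinship(ped, "B", "B")$kinship, 0.5)  # non-inbred self
  # mother and son (sire unrelated to her)
  ms <- mother_son_ped()
  expect_identical(kinship(ms, "M", "S")$kinship, 0.25)
  expect_identical(inbreeding(ped, "A")$f, 0)          # founder
  expect_error(kinship(ped, "A", "nobody"), "unknown identifier")
})

test_that("relationship matrix matches the textbook trio and 1 + f diagonals", {
  ped <- pedigree(c("P", "Q", "C"), c(NA, NA, "P"), c(NA, NA, "Q"))
  A <- relationship_matrix(ped, c("P", "Q", "C"))
  expect_equal(diag(A), c(P = 1, Q = 1, C = 1))
  expect_equal(A["P", "Q"], 0)
  expect_equal(A["P", "C"], 0.5)
  expect_equal(A["Q", "C"], 0.5)
  # child of half-sibs: diagonal 1 + 0.125
  expect_equal(unname(relationship_matrix(halfsib_ped(), "X")[1, 1]), 1.125)
})

test_that("recursive kinship equals the tabular A matrix on random pedigrees", {
  for (seed in 1:3) {
    ped <- random_pedigree(n_founders = 20, n_gen = 4, per_gen = 30,
                           seed = seed)
    ids <- ped_ids(ped)
    expect_lte(length(ids), 200L)
    A <- relationship_matrix(ped, ids)
    n <- length(ids)
    pick <- cbind(sample(n, 400, replace = TRUE), sample(n, 400, replace = TRUE))
    k <- kinship(ped, ids[pick[, 1]], ids[pick[, 2]])
    expect_lt(max(abs(2 * k - A[pick])), 1e-9)
    # symmetry and f = kinship of parents
    expect_lt(max(abs(A - t(A))), 1e-12)
    f <- inbreeding(ped, ids)
    both <- !is.na(ped$records$sire) & !is.na(ped$records$dam)
    fk <- kinship(ped, ped$records$sire[both], ped$records$dam[both])
    expect_equal(f[both], fk, tolerance = 1e-12)
    # f values on finite pedigrees are dyadic rationals
    expect_equal(f * 2^20, round(f * 2^20), tolerance = 1e-12)
  }
})

test_that("gene dropping agrees with exact kinship and is reproducible", {
  gp <- grandmother_ped()
  gd <- gene_drop_kinship(gp, "GM", "G", n_reps = 100000L, seed = 7)
  expect_lt(abs(gd$estimate - 0.125), 3 * gd$se)
  gd2 <- gene_drop_kinship(gp, "GM", "G", n_reps = 100000L, seed = 7)
  expect_identical(gd$estimate, gd2$estimate)
  # two founders are never identical by descent
  expect_identical(
    gene_drop_kinship(parent_offspring_ped(), "A", "B",
                      n_reps = 1000L, seed = 1)$estimate, 0)
  # mother-son at scale
  ms <- mother_son_ped()
  gms <- gene_drop_kinship(ms, "M", "S", n_reps = 100000L, seed = 5)
  expect_lt(abs(gms$estimate - 0.25), 3 * gms$se)
})

test_that("gene dropping tracks exact kinship over random pairs", {
  ped <- random_pedigree(n_founders = 16, n_gen = 4, per_gen = 25, seed = 9)
  ids <- ped_ids(ped)
  set.seed(42)
  pairs <- cbind(sample(ids, 50, replace = TRUE), sample(ids, 50, replace = TRUE))
  exact <- kinship(ped, pairs[, 1], pairs[, 2])
  for (r in seq_len(nrow(pairs))) {
    gd <- gene_drop_kinship(ped, pairs[r, 1], pairs[r, 2],
                            n_reps = 100000L, seed = 100 + r)
    se <- max(gd$se, sqrt(0.25 / gd$n_reps))  # floor for p near 0
    expect_lt(abs(gd$estimate - exact[r]), 4 * se)
  }
})

test_that("grandparent counts and completeness restriction behave", {
  gp <- grandmother_ped()
  expect_identical(known_grandparent_count(gp, "GM"), 0L)   # founder
  # both parents founders: no recorded grandparents
  trio <- pedigree(c("P", "Q", "C"), c(NA, NA, "P"), c(NA, NA, "Q"))
  expect_identical(known_grandparent_count(trio, "C"), 0L)
  # full two-generation ancestry
  ped4 <- pedigree(
    id   = c("gf1", "gm1", "gf2", "gm2", "pa", "ma", "kid"),
    sire = c(NA, NA, NA, NA, "gf1", "gf2", "pa"),
    dam  = c(NA, NA, NA, NA, "gm1", "gm2", "ma"))
  expect_identical(known_grandparent_count(ped4, "kid"), 4L)
  expect_identical(restrict_pedigree(ped4, 4), "kid")

  st <- small_study()
  sets <- lapply(0:4, function(m) restrict_pedigree(st$pedigree, m))
  for (m in 1:4) expect_true(all(sets[[m + 1]] %in% sets[[m]]))
  all4 <- known_grandparent_count(st$pedigree, sets[[5]])
  if (length(all4)) expect_true(all(all4 == 4L))
})

test_that("tighter restriction weakly raises the inbred fraction", {
  st <- default_study()
  su <- summarize_study(st)
  fr <- su$prop_inbred_by_restriction
  # excluding founder-parent offspring removes mostly f = 0 individuals
  expect_gte(fr[["min_gp_3"]] + 1e-12, fr[["min_gp_0"]])
  expect_gte(fr[["min_gp_4"]] + 1e-12, fr[["min_gp_1"]])
})

test_that("relationship classification labels the canonical routes", {
  ms <- mother_son_ped()
  expect_identical(classify_relationship(ms, "S", "M"), "mother_son")
  gp <- grandmother_ped()
  expect_identical(classify_relationship(gp, "G", "GM"), "grandmother_grandson")
  expect_identical(kinship(gp, "G", "GM")$kinship, 0.125)
  trio <- pedigree(c("P", "Q", "C"), c(NA, NA, "P"), c(NA, NA, "Q"))
  expect_identical(classify_relationship(trio, "P", "Q"), "unrelated")
  hs <- halfsib_ped()
  expect_identical(classify_relationship(hs, "H1", "H2"), "paternal_half_sib")
  # father-daughter orientation
  expect_identical(classify_relationship(trio, "P", "C"), "father_daughter")
  # full sibs
  fs <- pedigree(c("P", "Q", "B1", "B2"), c(NA, NA, "P", "P"),
                 c(NA, NA, "Q", "Q"))
  expect_identical(classify_relationship(fs, "B1", "B2"), "full_sib")
  # related but no named route: uncle-niece
  un <- pedigree(
    id   = c("P", "Q", "U", "M", "F2", "N"),
    sire = c(NA, NA, "P", "P", NA, "F2"),
    dam  = c(NA, NA, "Q", "Q", NA, "M"))
  expect_identical(classify_relationship(un, "U", "N"), "other_related")
})
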