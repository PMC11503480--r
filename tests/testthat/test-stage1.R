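test_that("profile_similarity matches hand-computed values", {
  q <- domain_profile("q", c(A = 1, B = 2, C = 3))
  expect_equal(profile_similarity(q, q), 1.0)
  expect_equal(profile_similarity(domain_profile("q", c(A = 1, B = 2)),
                                  domain_profile("r", c(A = 1, C = 3))), 0.5)
  expect_equal(profile_similarity(domain_profile("q", c(A = 2)),
                                  domain_profile("r", c(A = 3))), 0.0)
  expect_error(profile_similarity(domain_profile("q"), q), "empty")
})

test_that("profile_similarity agrees with a brute-force oracle", {
  set.seed(101)
  for (i in 1:200) {
    q <- random_profile("q")
    r <- random_profile("r")
    expect_equal(profile_similarity(q, r), oracle_similarity(q, r))
    expect_equal(profile_similarity(q, r), profile_similarity(r, q))
  }
})

test_that("knn_search ranks by similarity with deterministic tie-breaks", {
  mk_db <- function(profiles) {
    reference_db(lapply(profiles, reference_entry, superkingdom = "bacteria"),
                 list(bacteria = "A"))
  }
  q <- domain_profile("q", c(A = 1, B = 1, C = 1, D = 1))
  db <- mk_db(list(
    domain_profile("r1", c(A = 1, B = 1, C = 1, D = 1)),   # sim 1
    domain_profile("r2", c(A = 1, B = 1, X = 1, Y = 1)),   # sim 0.5
    domain_profile("r3", c(X = 1, Y = 2, Z = 3, W = 1))))  # sim 0
  nb <- knn_search(q, db, K = 2)
  expect_identical(nb$genome_id, c("r1", "r2"))
  expect_equal(nb$similarity, c(1, 0.5))
  expect_true(all(diff(nb$similarity) <= 0))

  # tie: equal similarity resolved by genome_id ascending
  db_tie <- mk_db(list(domain_profile("zz", c(A = 1)),
                       domain_profile("aa", c(A = 1))))
  expect_identical(knn_search(domain_profile("q", c(A = 1)), db_tie, 1)$genome_id,
                   "aa")
  expect_error(knn_search(q, db, K = 0), "at least 1")
  expect_warning(knn_search(q, db, K = 5), "only 3")
})

test_that("extract_markers is the equal-nonzero-count intersection", {
  n1 <- domain_profile("n1", c(A = 1, B = 2))
  expect_identical(extract_markers(list(n1)), c(A = 1, B = 2))
  n2 <- domain_profile("n2", c(A = 1, B = 3, C = 1))
  n3 <- domain_profile("n3", c(A = 1, B = 2, C = 1))
  expect_identical(extract_markers(list(n3, n2)), c(A = 1, C = 1))
  expect_identical(length(extract_markers(list(domain_profile("x", c(A = 1)),
                                               domain_profile("y", c(B = 1))))),
                   0L)
  set.seed(102)
  for (i in 1:100) {
    nbs <- lapply(seq_len(sample(1:5, 1)), function(j)
      random_profile(paste0("n", j), n_fam = 20, max_count = 3))
    expect_identical(extract_markers(nbs), oracle_markers(nbs))
  }
})

test_that("stage1_estimate reproduces the marker-count arithmetic", {
  markers3 <- c(A = 1, B = 1, C = 1)
  perfect <- stage1_estimate(domain_profile("q", c(A = 1, B = 1, C = 1)), markers3)
  expect_equal(perfect$completeness, 1.0)
  expect_equal(perfect$contamination, 0.0)

  est <- stage1_estimate(domain_profile("q", c(A = 2, B = 1, C = 1)), markers3)
  expect_equal(est$contamination, 1 / 3)
  expect_equal(est$completeness, 1.0)   # 4/3 - 1/3

  est2 <- stage1_estimate(domain_profile("q", c(A = 1, B = 1)),
                          c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(est2$contamination, 0.0)
  expect_equal(est2$completeness, 0.5)

  expect_error(stage1_estimate(domain_profile("q", c(A = 1)), numeric(0)),
               "no markers")

  set.seed(103)
  for (i in 1:100) {
    q <- random_profile("q", n_fam = 30)
    mk <- setNames(sample(3, 10, replace = TRUE), sprintf("F%02d", sample(30, 10)))
    est <- stage1_estimate(q, mk)
    orc <- oracle_estimate(q, mk)
    expect_equal(est$contamination, orc$cont)
    expect_equal(est$completeness_raw, orc$comp)
    # literal identity: comp_raw = mean ratio - cont
    expect_equal(est$completeness_raw + est$contamination,
                 mean(profile_counts(q, names(mk)) / mk))
  }
})

test_that("deleting markers never raises completeness; duplicating never lowers contamination", {
  set.seed(104)
  mk <- setNames(rep(1, 20), sprintf("M%02d", 1:20))
  full <- domain_profile("q", mk)
  base <- stage1_estimate(full, mk)
  for (i in 1:20) {
    drop <- sample(20, sample(10, 1))
    est <- stage1_estimate(domain_profile("q", mk[-drop]), mk)
    expect_lte(est$completeness_raw, base$completeness_raw)
    dup <- sample(20, sample(10, 1))
    counts <- mk; counts[dup] <- counts[dup] + 1
    est2 <- stage1_estimate(domain_profile("q", counts), mk)
    expect_gte(est2$contamination, base$contamination)
  }
})

test_that("prefilter rejects only when both marker sets fall below threshold", {
  bact <- sprintf("B%02d", 1:25)
  arch <- sprintf("A%02d", 1:25)
  db <- reference_db(list(reference_entry(domain_profile("r", c(B01 = 1)),
                                          "bacteria")),
                     list(bacteria = bact, archaea = arch))
  full <- domain_profile("q", setNames(rep(1, 25), bact))
  expect_identical(prefilter(full, db)$status, "pass")
  none <- domain_profile("q", c(OTHER = 1))
  expect_identical(prefilter(none, db)$status, "rejected")
  # 3/25 = 12% of one set only -> pass
  some <- domain_profile("q", setNames(rep(1, 3), bact[1:3]))
  expect_identical(prefilter(some, db)$status, "pass")
  # just below 10% on both -> rejected
  two <- domain_profile("q", setNames(rep(1, 2), c(bact[1], arch[1])))
  expect_identical(prefilter(two, db)$status, "rejected")
})

test_that("routing applies the strict 60%/30% rule", {
  expect_identical(route(0.55, 0.00), "final")
  expect_identical(route(0.95, 0.35), "final")
  expect_identical(route(0.90, 0.10), "refine")
  # boundary values are inside the stage-II range (strict inequalities)
  expect_identical(route(0.60, 0.30), "refine")
})

test_that("a query identical to a reference is recovered perfectly", {
  db <- small_world_db()
  for (gid in names(db$entries)[1:3]) {
    s1 <- stage1_analyze(db$entries[[gid]]$profile, db, K = 1)
    expect_identical(s1$neighbors$genome_id[1], gid)
    expect_equal(s1$neighbors$similarity[1], 1.0)
    expect_equal(s1$completeness, 1.0)
    expect_equal(s1$contamination, 0.0)
  }
})

test_that("stage1_analyze flags empty marker sets instead of fabricating estimates", {
  # two references with no agreeing nonzero counts and a query passing prefilter
  e1 <- reference_entry(domain_profile("r1", c(M1 = 1, A = 2)), "bacteria")
  e2 <- reference_entry(domain_profile("r2", c(M1 = 2, B = 2)), "bacteria")
  db <- reference_db(list(e1, e2), list(bacteria = c("M1")))
  s1 <- stage1_analyze(domain_profile("q", c(M1 = 1)), db, K = 2)
  expect_identical(s1$route, "rejected")
  expect_match(s1$reason, "no markers")
})

test_that("lca_taxonomy finds the deepest common ancestor", {
  # toy 5-node tree: 1 root; 2,3 children of 1; 4,5 children of 2
  parents <- c("1" = 1, "2" = 1, "3" = 1, "4" = 2, "5" = 2)
  expect_identical(lca_taxonomy(c(4), parents), 4)
  expect_identical(lca_taxonomy(c(4, 5), parents), 2)
  expect_identical(lca_taxonomy(c(4, 4, 4), parents), 4)
  expect_identical(lca_taxonomy(c(4, 3), parents), 1)
  expect_error(lca_taxonomy(c(99), parents), "unknown taxid")
  expect_error(lca_taxonomy(integer(0), parents), "no neighbor")
})
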