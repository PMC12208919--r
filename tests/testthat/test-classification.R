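# A 6-sample presence design exercised throughout: rows are clonotypes with
# hand-chosen presence patterns over ctrl (s1-s3) and mut (s4-s6).
dependence_fixture <- function() {
  counts <- rbind(
    c(2, 1, 3, 0, 0, 0),  # in 3 ctrl, 0 mut -> recurrent, dependent
    c(1, 1, 0, 1, 0, 0),  # 2 ctrl + 1 mut   -> recurrent, shared
    c(0, 0, 0, 2, 5, 1),  # 0 ctrl, 3 mut    -> recurrent, newcomer
    c(9, 0, 0, 0, 0, 4),  # 2 samples only   -> not recurrent
    c(1, 1, 1, 1, 1, 1)   # everywhere       -> recurrent, shared
  )
  colnames(counts) <- paste0("s", 1:6)
  make_table(counts, groups = rep(c("ctrl", "mut"), each = 3))
}

test_that("recurrence thresholds presence across samples", {
  tab <- dependence_fixture()
  rec <- recurrent_clonotypes(tab, min_samples = 3)
  expect_setequal(rec, rownames(tab$counts)[c(1, 2, 3, 5)])
  expect_setequal(recurrent_clonotypes(tab, min_samples = 1),
                  rownames(tab$counts))
  expect_error(recurrent_clonotypes(tab, min_samples = 0), "integer")
  expect_error(recurrent_clonotypes(tab, min_samples = 7), "min_samples")
  # counts beyond presence do not matter
  tab2 <- tab; tab2$counts <- tab$counts * 50L
  expect_identical(recurrent_clonotypes(tab2), rec)
})

test_that("dependence classes partition the recurrent set", {
  tab <- dependence_fixture()
  rec <- recurrent_clonotypes(tab)
  dep <- classify_dependence(tab, rec, "ctrl", "mut")
  keys <- rownames(tab$counts)
  expect_setequal(dep$sets$dependent, keys[1])
  expect_setequal(dep$sets$newcomer, keys[3])
  expect_setequal(dep$sets$shared, keys[c(2, 5)])
  with(dep$sets, {
    expect_setequal(c(dependent, shared, newcomer), recurrent)
    expect_equal(length(recurrent_a) + length(recurrent_b) - length(shared),
                 length(recurrent))
  })
  expect_error(classify_dependence(tab, rec, "ctrl", "ctrl"), "overlap")
  expect_error(classify_dependence(tab, rec, "ctrl", "nope"), "no samples")
  expect_error(classify_dependence(tab, c(rec, "x|y|z"), "ctrl", "mut"),
               "absent")
})

test_that("dependence is invariant to sample order and count magnitude", {
  set.seed(5)
  st <- simulate_study(sim_config(s_shared = 60, s_dependent = 30,
                                  s_newcomer = 20, reads = 1500), seed = 5)
  tab <- st$table
  rec <- recurrent_clonotypes(tab)
  d1 <- classify_dependence(tab, rec, "ctrl", "mut")
  perm <- sample(ncol(tab$counts))
  tab2 <- tab
  tab2$counts <- tab$counts[, perm]
  tab2$samples <- tab$samples[perm, ]
  rownames(tab2$samples) <- NULL
  d2 <- classify_dependence(tab2, rec, "ctrl", "mut")
  expect_identical(d1$labels, d2$labels)
})

test_that("CD5 classification demands recurrence in one extreme and absence in the other", {
  counts <- rbind(
    c(1, 2, 1, 0, 0, 0, 0, 0),  # 3/4 lo, 0 hi -> natural_lo
    c(1, 1, 1, 1, 1, 0, 0, 0),  # 4/4 lo, 1 hi -> unassigned
    c(0, 0, 0, 0, 3, 1, 2, 2),  # 0 lo, 4/4 hi -> natural_hi
    c(1, 0, 0, 0, 0, 0, 1, 1)   # 1 lo, 2 hi   -> unassigned
  )
  colnames(counts) <- c(paste0("lo", 1:4), paste0("hi", 1:4))
  tab <- make_table(counts, subsets = rep(c("CD5lo", "CD5hi"), each = 4))
  cd5 <- classify_cd5(tab, "CD5lo", "CD5hi")
  keys <- rownames(tab$counts)
  expect_setequal(cd5$sets$natural_lo, keys[1])
  expect_setequal(cd5$sets$natural_hi, keys[3])
  expect_length(intersect(cd5$sets$natural_lo, cd5$sets$natural_hi), 0)
  expect_error(classify_cd5(tab, "CD5lo", "CD5lo"), "overlap")
})

test_that("cross-assignment inherits dependence classes over both denominators", {
  tab <- dependence_fixture()
  dep <- classify_dependence(tab, recurrent_clonotypes(tab), "ctrl", "mut")
  keys <- rownames(tab$counts)
  xa <- cross_assign(keys[1], dep)   # the dependent clone
  expect_equal(unname(xa$fraction_matched["dependent"]), 1)
  xa2 <- cross_assign(c(keys[1], keys[2], "no|such|clone"), dep)
  expect_equal(xa2$n_matched, 2L)
  expect_equal(xa2$n_unmatched, 1L)
  expect_equal(unname(xa2$fraction_matched["dependent"]), 0.5)
  expect_equal(unname(xa2$fraction_all["dependent"]), 1 / 3)
  expect_warning(xa3 <- cross_assign("no|such|clone", dep), "no query")
  expect_equal(xa3$n_matched, 0L)
  expect_error(cross_assign(character(0), dep), "empty")
})

test_that("top expanded clonotypes rank by mean frequency with deterministic ties", {
  counts <- cbind(a = c(50, 30, 20, 0), b = c(40, 40, 10, 10))
  tab <- make_table(counts)
  top <- top_expanded(tab, k = 2)
  expect_equal(nrow(top), 2L)
  expect_equal(top$mean_freq[1], mean(c(0.5, 0.4)))
  expect_true(all(diff(top$mean_freq) <= 0))
  # exact tie: clonotypes 3 and 4 tie on pooled counts in a one-sample table
  tie <- make_table(matrix(c(5, 5, 2), 3, dimnames = list(NULL, "s")))
  t2 <- top_expanded(tie, k = 1)
  expect_equal(t2$key, sort(rownames(tie$counts)[1:2])[1])
  expect_warning(top_expanded(tie, k = 10), "exceeds")
})

test_that("subrepertoire diversity restricts counts before the Hill computation", {
  counts <- cbind(s1 = c(4, 2, 2), s2 = c(0, 0, 8))
  tab <- make_table(counts)
  keys <- rownames(tab$counts)
  all_d <- subrepertoire_diversity(tab, keys)
  expect_equal(unname(all_d["s1"]), hill_diversity(c(4, 2, 2)))
  last_two <- subrepertoire_diversity(tab, keys[2:3])
  expect_equal(unname(last_two["s1"]), 2)        # equal abundances (2,2)
  only_first <- subrepertoire_diversity(tab, keys[1])
  expect_equal(unname(only_first["s1"]), 1)
  expect_true(is.na(only_first["s2"]))           # empty restriction
  expect_error(subrepertoire_diversity(tab, character(0)), "empty")
})

test_that("planted public paired clones are recovered exactly", {
  for (np in c(0L, 1L, 5L)) {
    sim <- simulate_paired(n_public = np, seed = 31 + np)
    sets <- aggregate_paired(sim$cells)
    pub <- public_paired(sets, "ctrl", "mut")
    truth_pub <- sim$truth$key[sim$truth$type == "public"]
    got <- if (nrow(pub)) paste(
      clonotype_key(normalize_gene_calls(pub$alpha_v),
                    normalize_gene_calls(pub$alpha_j),
                    toupper(pub$alpha_cdr3)),
      clonotype_key(normalize_gene_calls(pub$beta_v),
                    normalize_gene_calls(pub$beta_j),
                    toupper(pub$beta_cdr3)), sep = "||") else character(0)
    expect_setequal(got, truth_pub)
  }
})
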