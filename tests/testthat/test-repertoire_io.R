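test_that("the reader returns one read per row and does not deduplicate", {
  reads <- rbind(
    reads_row(umi = "u1"),
    reads_row(umi = "u1"),  # duplicate (sample, umi): still two rows
    reads_row(umi = "u2", v_call = "TRAV14-1,TRAV14D-1")
  )
  path <- write_reads_tsv(reads)
  got <- read_rearrangements(path)
  expect_equal(nrow(got), 3L)
  expect_equal(got$n_v_calls, c(1L, 1L, 2L))
  expect_true(got$paralog_ambiguous[3])

  empty <- read_rearrangements(write_reads_tsv(reads[0, , drop = FALSE]))
  expect_equal(nrow(empty), 0L)
})

test_that("the reader names missing columns and normalises gene calls", {
  reads <- reads_row(v_call = "trav14-1*01", j_call = "TRAJ33*02")
  got <- read_rearrangements(write_reads_tsv(reads))
  expect_equal(got$v_call, "TRAV14-1")
  expect_equal(got$j_call, "TRAJ33")

  bad <- reads[, setdiff(names(reads), "j_call")]
  expect_error(read_rearrangements(write_reads_tsv(bad)), "j_call")
  expect_error(read_rearrangements(tempfile()), "not found")
})

test_that("aggregation collapses UMIs, conserves molecules and keys by clonotype", {
  reads <- rbind(
    reads_row(umi = "u1"), reads_row(umi = "u1"),   # one molecule
    reads_row(umi = "u2"), reads_row(umi = "u3"),
    reads_row(umi = "u4", v_call = "TRAV2", junction_aa = "CGGGF"),
    reads_row(umi = "u5", v_call = "TRAV2", junction_aa = "CGGGF")
  )
  tab <- aggregate_bulk(read_rearrangements(write_reads_tsv(reads)))
  expect_s3_class(tab, "abundance_table")
  expect_equal(sum(tab$counts), 5L)   # 6 reads, 5 unique molecules
  expect_equal(unname(tab$counts[, "s1"]),
               c(3L, 2L)[order(tab$clonotypes$v_gene)])
  # column sum equals number of unique molecules in the sample
  expect_equal(colSums(tab$counts), c(s1 = 5L))
})

test_that("UMI conflicts resolve by majority with lexicographic tie-break", {
  reads <- rbind(
    reads_row(umi = "u1", v_call = "TRAV2"),
    reads_row(umi = "u1", v_call = "TRAV2"),
    reads_row(umi = "u1", v_call = "TRAV1"),  # minority: loses
    reads_row(umi = "u2", v_call = "TRAV9"),
    reads_row(umi = "u2", v_call = "TRAV3")   # tie: smallest key wins
  )
  tab <- aggregate_bulk(read_rearrangements(write_reads_tsv(reads)))
  expect_equal(rownames(tab$counts),
               clonotype_key(c("TRAV2", "TRAV3"), "TRAJ1", "CAASF"))
  expect_equal(attr(tab, "umi_conflict_rate"), 1)
})

test_that("paralog-ambiguous molecules are kept by default and dropped on request", {
  reads <- rbind(
    reads_row(umi = "u1", v_call = "TRAV14-1,TRAV14D-1"),
    reads_row(umi = "u2"), reads_row(umi = "u3")
  )
  parsed <- read_rearrangements(write_reads_tsv(reads))
  kept <- aggregate_bulk(parsed)
  expect_equal(sum(kept$counts), 3L)
  expect_true("TRAV14-1,TRAV14D-1" %in% kept$clonotypes$v_gene)

  dropped <- aggregate_bulk(parsed, drop_paralog_ambiguous = TRUE)
  expect_equal(sum(dropped$counts), 2L)
  expect_equal(unname(dropped$paralog_excluded["s1"]), 1 / 3)
  # monotonicity: dropping never increases any retained count
  common <- intersect(rownames(kept$counts), rownames(dropped$counts))
  expect_true(all(dropped$counts[common, ] <= kept$counts[common, ]))
})

test_that("aggregation is invariant to read order and validates inputs", {
  set.seed(42)
  reads <- rbind(
    reads_row(umi = sprintf("u%d", 1:6), v_call = rep(c("TRAV1", "TRAV5"), 3)),
    reads_row(sample_id = "s2", umi = sprintf("u%d", 1:4), v_call = "TRAV5")
  )
  parsed <- read_rearrangements(write_reads_tsv(reads))
  t1 <- aggregate_bulk(parsed)
  t2 <- aggregate_bulk(parsed[sample(nrow(parsed)), ])
  expect_identical(t1$counts, t2$counts)

  expect_error(
    aggregate_bulk(parsed,
                   samples = data.frame(sample_id = "s1")),
    "unknown sample")
  bad <- parsed; bad$cdr3_aa[1] <- ""
  expect_error(aggregate_bulk(bad), "empty cdr3_aa")
})

test_that("abundance TSV round-trips tables including metadata and empties", {
  tab <- make_table(matrix(c(4, 0, 2, 6), 2,
                           dimnames = list(NULL, c("a", "b"))),
                    groups = c("ctrl", "mut"), subsets = c("M2", "M2"))
  path <- tempfile(fileext = ".tsv")
  write_abundance(tab, path)
  back <- read_abundance(path)
  expect_identical(back$counts, tab$counts)
  expect_identical(back$samples, tab$samples)
  expect_identical(back$clonotypes, tab$clonotypes)

  empty <- abundance_table(matrix(0L, 0, 2,
                                  dimnames = list(NULL, c("a", "b"))),
                           data.frame(v_gene = character(),
                                      j_gene = character(),
                                      cdr3_aa = character()),
                           data.frame(sample_id = c("a", "b")))
  p2 <- tempfile(); write_abundance(empty, p2)
  expect_equal(nrow(read_abundance(p2)$counts), 0L)

  writeLines(c("v_gene\tj_gene\tcdr3_aa\ts1", "TRAV1\tTRAJ1\tCAF\t-2"),
             p3 <- tempfile())
  expect_error(read_abundance(p3), "nonnegative")
})

test_that("paired aggregation counts a clonotype once per mouse and filters frames", {
  cell <- function(mouse, group, cdr3b = "CASSF", ifa = TRUE, ifb = TRUE) {
    data.frame(mouse_id = mouse, group = group, alpha_v = "TRAV14-1",
               alpha_cdr3 = "CAASF", alpha_j = "TRAJ33", beta_v = "TRBV5",
               beta_cdr3 = cdr3b, beta_j = "TRBJ1-1",
               in_frame_alpha = ifa, in_frame_beta = ifb,
               stringsAsFactors = FALSE)
  }
  cells <- rbind(cell("m1", "ctrl"), cell("m1", "ctrl"), cell("m1", "ctrl"),
                 cell("m2", "mut"),
                 cell("m3", "mut", ifb = FALSE))
  sets <- aggregate_paired(cells)
  expect_equal(nrow(sets$clonotypes), 1L)
  expect_equal(sets$clonotypes$n_mice, 2L)       # once per mouse, two mice
  expect_equal(sets$rejected$reason, "beta chain out of frame")
  pub <- public_paired(sets, "ctrl", "mut")
  expect_equal(nrow(pub), 1L)
  expect_equal(pub$n_mice_a, 1)
  expect_equal(pub$n_mice_b, 1)
})
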