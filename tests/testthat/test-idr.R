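# consensus IDR calling, class comparisons, composition enrichment

test_that("consensus and run-length boundaries are strict", {
  # 4 predictors, exactly 3 agreeing (75%) never passes the strict cut
  calls <- cbind(TRUE, TRUE, TRUE, FALSE)[rep(1, 50), ]
  expect_equal(nrow(call_idrs(calls)$intervals), 0)
  # run of exactly 10 consensus residues is not an IDR; 11 is
  mk <- function(run) {
    m <- matrix(FALSE, 30, 4)
    m[10:(10 + run - 1), ] <- TRUE
    m
  }
  expect_equal(nrow(call_idrs(mk(10))$intervals), 0)
  iv <- call_idrs(mk(11))$intervals
  expect_equal(iv, data.frame(start = 10L, end = 20L))
})

test_that("a fully disordered protein is one interval of proportion 1", {
  res <- call_idrs(matrix(TRUE, 100, 5))
  expect_equal(res$intervals, data.frame(start = 1L, end = 100L))
  expect_equal(res$idr_proportion, 1)
})

test_that("interval calling matches the naive-scan oracle", {
  set.seed(71)
  for (i in 1:25) {
    calls <- matrix(runif(200 * 6) < 0.55, 200, 6)
    frac <- sample(c(0.5, 0.75, 0.9), 1)
    run <- sample(c(5, 10, 15), 1)
    got <- call_idrs(calls, frac, run)$intervals
    want <- naive_idr_scan(calls, frac, run)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
    # predictor column order is irrelevant
    perm <- call_idrs(calls[, sample(6)], frac, run)$intervals
    expect_identical(got, perm)
  }
})

test_that("tightening thresholds never lengthens total IDR coverage", {
  set.seed(72)
  total_len <- function(iv) sum(iv$end - iv$start + 1L)
  for (i in 1:10) {
    calls <- matrix(runif(300 * 8) < 0.6, 300, 8)
    l1 <- total_len(call_idrs(calls, 0.5, 10)$intervals)
    l2 <- total_len(call_idrs(calls, 0.75, 10)$intervals)
    l3 <- total_len(call_idrs(calls, 0.75, 20)$intervals)
    expect_lte(l2, l1)
    expect_lte(l3, l2)
  }
})

test_that("planted IDRs are recovered exactly at full agreement", {
  d <- gen_disorder(n_proteins = 30, agreement = 1,
                    false_call_rate = 0, seed = 73)
  for (i in seq_len(30)) {
    iv <- call_idrs(d$profiles[[i]])$intervals
    expect_equal(nrow(iv), 1)
    expect_equal(iv$start, d$truth$idr_start[i])
    expect_equal(iv$end, d$truth$idr_end[i])
  }
})

test_that("class comparisons use rank-sum with Holm adjustment", {
  set.seed(74)
  # identical distributions: no rejections
  props <- c(runif(50), runif(50), runif(50))
  classes <- rep(c("stabilized", "destabilized", "unaffected"), each = 50)
  same <- idr_proportion_by_class(props, classes)
  expect_equal(nrow(same), 3)
  expect_true(all(same$p_adjusted > 0.05))
  # planted 0.2 upward shift, n = 70 vs 5811
  hits <- 0
  n_rep <- 10
  for (r in 1:n_rep) {
    p_stab <- pmin(runif(70, 0.2, 0.7) + 0.2, 1)
    p_unaf <- runif(5811, 0.2, 0.7)
    res <- idr_proportion_by_class(
      c(p_stab, p_unaf),
      rep(c("stabilized", "unaffected"), c(70, 5811)))
    hits <- hits + (res$p_adjusted[1] < 0.05)
  }
  expect_gte(hits / n_rep, 0.95)
  # tiny class is skipped, single class yields nothing
  sk <- idr_proportion_by_class(c(0.1, 0.2, runif(10)),
                                rep(c("a", "b"), c(2, 10)))
  expect_true(sk$skipped[1])
  expect_equal(nrow(idr_proportion_by_class(runif(5), rep("a", 5))), 0)
})

test_that("composition enrichment scores behave at the identities", {
  set.seed(75)
  seqs <- vapply(1:40, function(i) {
    paste(sample(c("A", "R", "N", "D", "G", "L", "S"), 80,
                 replace = TRUE), collapse = "")
  }, character(1))
  same <- composition_enrichment(seqs, seqs, n_boot = 20, seed = 1)
  expect_equal(same$score[same$f_background > 0],
               rep(0, sum(same$f_background > 0)))
  # reconstruction identity: (1 + score) * f_bg = f_group
  set.seed(76)
  other <- vapply(1:30, function(i) {
    paste(sample(c("A", "R", "G", "L"), 60, replace = TRUE),
          collapse = "")
  }, character(1))
  ce <- composition_enrichment(other, seqs, n_boot = 0)
  ok <- !is.na(ce$score)
  expect_equal((1 + ce$score[ok]) * ce$f_background[ok], ce$f_group[ok],
               tolerance = 1e-12)
  # complete depletion scores exactly -1
  no_w <- c("AAAA", "GGGG")
  with_w <- c("WWAA", "WGGG")
  ce2 <- composition_enrichment(no_w, with_w, n_boot = 0)
  expect_equal(ce2$score[ce2$aa == "W"], -1)
  # constructed doubling: group R frequency exactly twice the background
  bg <- rep(paste0("R", strrep("A", 19)), 30)       # f_R = 0.05
  grp <- rep(paste0("RR", strrep("A", 18)), 30)     # f_R = 0.10
  ce3 <- composition_enrichment(grp, bg, n_boot = 0)
  expect_equal(ce3$score[ce3$aa == "R"], 1, tolerance = 1e-12)
  expect_lt(ce3$p_adjusted[ce3$aa == "R"], 0.05)
})

test_that("a planted 2x arginine enrichment is detected", {
  d <- gen_disorder(n_proteins = 400,
                    class_probs = c(stabilized = 0.25, destabilized = 0.25,
                                    unaffected = 0.5),
                    agreement = 1, enrich_factor = 2, seed = 77)
  idrs <- lapply(names(d$profiles), function(id) {
    iv <- call_idrs(d$profiles[[id]])$intervals
    substr(d$sequences[[id]], iv$start[1], iv$end[1])
  })
  names(idrs) <- names(d$profiles)
  stab <- unlist(idrs[d$truth$class == "stabilized"])
  ce <- composition_enrichment(stab, unlist(idrs), n_boot = 100, seed = 2)
  # the background pool includes the enriched group itself, so the
  # recovered score sits well below the planted 2x but clearly positive
  r_row <- ce[ce$aa == "R", ]
  expect_gt(r_row$score, 0.15)
  expect_lt(r_row$p_adjusted, 0.05)
  expect_gt(r_row$boot_sd, 0)
})

test_that("residue counting is exact and flags non-standard letters", {
  expect_equal(count_residue("MMM", "M")$count, 3)
  cr <- count_residue("MXSQM", "M")
  expect_equal(cr$count, 2)
  expect_equal(cr$length, 5)
  expect_equal(cr$nonstandard$X, 2 - 1)  # one X reported
})

test_that("disorder tracks and IDR intervals round-trip through files", {
  d <- gen_disorder(n_proteins = 5, agreement = 1, false_call_rate = 0,
                    seed = 78)
  path <- tempfile(fileext = ".tsv")
  rows <- do.call(rbind, lapply(names(d$profiles), function(id) {
    m <- d$profiles[[id]]
    expand.grid(residue_index = seq_len(nrow(m)),
                predictor_id = paste0("pred", seq_len(ncol(m))),
                stringsAsFactors = FALSE) |>
      transform(protein_id = id,
                call = as.integer(m[cbind(residue_index,
                                          as.integer(sub("pred", "",
                                                         predictor_id)))]))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tracks <- read_disorder_tracks(path)
  expect_equal(sort(names(tracks)), sort(names(d$profiles)))
  for (id in names(tracks)) {
    expect_equal(unname(tracks[[id]]), unname(d$profiles[[id]]))
  }
  out <- tempfile(fileext = ".tsv")
  sets <- lapply(d$profiles, call_idrs)
  write_idr_intervals(sets, out)
  back <- read.delim(out, comment.char = "#")
  expect_equal(nrow(back), 5)
  expect_equal(back$start, d$truth$idr_start)
  # FASTA round trip via Biostrings
  fa <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(d$sequences), "\n", d$sequences), fa)
  seqs <- read_fasta_sequences(fa)
  expect_equal(unname(seqs), unname(d$sequences))
})
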