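make_calls_df <- function(truth, called_idx, states) {
  # build an exon-level call table over the truth's index space
  J <- nrow(truth); I <- ncol(truth)
  df <- data.frame(
    subject = rep(colnames(truth), each = J),
    target_id = rep(rownames(truth), I),
    state = 1,
    called = FALSE,
    stringsAsFactors = FALSE
  )
  df$state[called_idx] <- states
  df$called[called_idx] <- TRUE
  df
}

empty_truth <- function(J, I) {
  matrix(1, J, I, dimnames = list(sprintf("T%04d", seq_len(J)),
                                  sprintf("S%02d", seq_len(I))))
}

test_that("a perfect caller scores FDR 0, TPR 1, MCC 1", {
  truth <- empty_truth(200, 4)
  truth[c(10, 50), 1] <- c(0.5, 2)
  idx <- which(as.vector(truth) != 1)
  calls <- make_calls_df(truth, idx, as.vector(truth)[idx])
  cf <- cnv_confusion(calls, truth)
  expect_equal(cf$FDR, rep(0, 3))
  expect_equal(cf$TPR, rep(1, 3))
  expect_equal(cf$MCC, rep(1, 3))
  expect_equal(cf$PPV, rep(1, 3))
})

test_that("the confusion counts reproduce a hand-worked MCC", {
  # TP = 9, FP = 1, FN = 1, TN = 989 -> MCC = 8900/9900, FDR = 0.1
  truth <- empty_truth(1000, 1)
  truth[1:10, 1] <- 2
  calls <- make_calls_df(truth, c(1:9, 20), rep(2, 10))
  cf <- cnv_confusion(calls, truth, stratum = "ALL")
  expect_identical(c(cf$TP, cf$FP, cf$TN, cf$FN), c(9L, 1L, 989L, 1L))
  expect_equal(cf$MCC, 8900 / 9900, tolerance = 1e-12)
  expect_equal(cf$FDR, 0.1)
  expect_equal(cf$PPV, 0.9)
  expect_equal(cf$BalAcc, (0.9 + 989 / 990) / 2)
})

test_that("degenerate denominators follow the stated conventions", {
  truth <- empty_truth(50, 2)
  truth[5, 1] <- 0.5
  calls <- make_calls_df(truth, integer(0), numeric(0))
  cf <- cnv_confusion(calls, truth, stratum = "ALL")
  expect_equal(cf$TPR, 0)   # one true variant, none called
  expect_equal(cf$FDR, 0)   # no positives: defined zero
  expect_equal(cf$MCC, 0)   # empty positive marginal

  # no true variants at all: TPR undefined
  truth0 <- empty_truth(50, 2)
  cf0 <- cnv_confusion(make_calls_df(truth0, integer(0), numeric(0)), truth0,
                       stratum = "ALL")
  expect_true(is.na(cf0$TPR))
})

test_that("direction must match: a deletion call on a duplication is an FP", {
  truth <- empty_truth(100, 1)
  truth[1, 1] <- 2
  calls <- make_calls_df(truth, 1, 0.5)  # flags the right exon, wrong side
  cf <- cnv_confusion(calls, truth, stratum = "ALL")
  expect_identical(cf$TP, 0L)
  expect_identical(cf$FP, 1L)
  # in the DEL stratum the duplication is not a condition positive
  cfd <- cnv_confusion(calls, truth, stratum = "DEL")
  expect_identical(cfd$TP, 0L)
  expect_identical(cfd$FP, 1L)
  # in the DUP stratum the call is not a positive, the exon is missed
  cfu <- cnv_confusion(calls, truth, stratum = "DUP")
  expect_identical(cfu$FN, 1L)
})

test_that("excluded targets shrink the evaluated set monotonically", {
  truth <- empty_truth(100, 2)
  truth[3, 1] <- 1.5
  calls <- make_calls_df(truth, 3, 1.5)
  cf_all <- cnv_confusion(calls, truth, stratum = "ALL")
  cf_masked <- cnv_confusion(calls, truth, stratum = "ALL",
                             exclude = rownames(truth)[1:10])
  expect_lt(cf_masked$n, cf_all$n)
  expect_identical(cf_masked$TP, 0L)  # the variant sat in the mask
  expect_error(cnv_confusion(transform(calls, subject = "nope"), truth),
               "mismatch")
})

test_that("overlap tallies enumerate set memberships", {
  a <- data.frame(subject = "S1", target_id = c("T1", "T2", "T3"),
                  direction = c("dup", "del", "dup"))
  expect_identical(overlap_sets(A = a, B = a)$region, "A&B")
  expect_identical(overlap_sets(A = a, B = a)$total, 3L)

  b <- data.frame(subject = "S1", target_id = c("T4", "T5"),
                  direction = c("dup", "del"))
  dj <- overlap_sets(A = a, B = b)
  expect_setequal(dj$region, c("A", "B"))
  expect_false(any(grepl("&", dj$region)))

  # hand-built three-set fixture with known memberships
  x <- data.frame(subject = "S1", target_id = c("T1", "T2", "T3"),
                  direction = "dup")
  y <- data.frame(subject = "S1", target_id = c("T2", "T3", "T4"),
                  direction = "dup")
  z <- data.frame(subject = "S1", target_id = c("T3", "T5"),
                  direction = "dup")
  ov <- overlap_sets(X = x, Y = y, Z = z)
  get <- function(r) ov$total[ov$region == r]
  expect_identical(get("X"), 1L)        # T1
  expect_identical(get("X&Y"), 1L)      # T2
  expect_identical(get("X&Y&Z"), 1L)    # T3
  expect_identical(get("Y"), 1L)        # T4
  expect_identical(get("Z"), 1L)        # T5
  expect_error(overlap_sets(A = a), "2 or 3")
})

test_that("depth sweeps are seeded, reproducible, and well-formed", {
  sw1 <- sweep_depths(depths = c(300 * 40, 300 * 150), replicates = 2,
                      subjects = 6, targets = 300, variant_prob = 1/100,
                      seed = 5)
  sw2 <- sweep_depths(depths = c(300 * 40, 300 * 150), replicates = 2,
                      subjects = 6, targets = 300, variant_prob = 1/100,
                      seed = 5)
  expect_identical(sw1$pooled, sw2$pooled)
  expect_identical(sw1$replicates, sw2$replicates)
  expect_identical(nrow(sw1$pooled), 2L)
  expect_identical(nrow(sw1$replicates), 4L)
  expect_true(all(c("TP", "FP", "TN", "FN", "TPR", "FDR", "MCC")
                  %in% names(sw1$pooled)))

  # zero-variant grid: TPR undefined, FDR driven by FP alone
  sw0 <- sweep_depths(depths = 300 * 40, replicates = 1, subjects = 6,
                      targets = 300, variant_prob = 0, seed = 9)
  expect_true(is.na(sw0$pooled$TPR))
  expect_equal(sw0$pooled$FDR, sw0$pooled$FP / max(1, sw0$pooled$FP))
})
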