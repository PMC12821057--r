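test_that("segment masks partition the window by interval arithmetic", {
  lm <- c(p_onset = 25L, qrs_onset = 100L, qrs_offset = 150L,
          t_offset = 325L)
  masks <- build_segment_masks(lm, W = 350)
  expect_length(masks, 350)
  expect_equal(as.integer(table(masks)[c("PR", "QRS", "STT", "TP")]),
               c(75L, 50L, 175L, 50L))  # TP = 25 + 25 flanks

  # degenerate empty PR still partitions
  lm2 <- c(p_onset = 100L, qrs_onset = 100L, qrs_offset = 150L,
           t_offset = 325L)
  m2 <- build_segment_masks(lm2, W = 350)
  expect_equal(sum(m2 == "PR"), 0L)
  expect_equal(length(m2), 350L)
  expect_false(anyNA(m2))

  expect_error(build_segment_masks(c(p_onset = 50L, qrs_onset = 20L,
                                     qrs_offset = 150L, t_offset = 325L),
                                   W = 350),
               "ordering")
})

test_that("saliency equals the central finite-difference oracle", {
  m <- build_model(tiny_spec(), input_length = 30, seed = 13)
  batch <- tiny_batch(W = 30, seed = 14)
  masks <- build_segment_masks(c(p_onset = 2L, qrs_onset = 8L,
                                 qrs_offset = 14L, t_offset = 24L),
                               W = 30)
  sal <- saliency_map(m, batch, masks = masks)
  expect_true(all(sal$values >= 0))
  expect_equal(dim(sal$values), c(30L, 12L))

  h <- 1e-3
  lead_of_group <- list(limb = 1:6, precordial = 7:12)
  fd_at <- function(g, r, c, hh) {
    bp <- batch; bp$groups[[g]][r, c] <- bp$groups[[g]][r, c] + hh
    bm <- batch; bm$groups[[g]][r, c] <- bm$groups[[g]][r, c] - hh
    (predict_lvm(m, bp) - predict_lvm(m, bm)) / (2 * hh)
  }
  worst <- 0; checked <- 0
  set.seed(15)
  while (checked < 100) {
    g <- sample(2, 1); r <- sample(30, 1); c <- sample(6, 1)
    fd <- fd_at(g, r, c, h)
    # skip intervals straddling a ReLU kink (secants at h, h/2 disagree)
    if (abs(fd - fd_at(g, r, c, h / 2)) > 1e-7 * max(abs(fd), 1)) next
    an <- sal$values[r, lead_of_group[[g]][c]]
    worst <- max(worst, abs(abs(fd) - an) / max(abs(fd), 1e-8))
    checked <- checked + 1
  }
  expect_lt(worst, 1e-3)
})

test_that("a constant model has zero saliency everywhere", {
  m <- build_model(tiny_spec(), input_length = 30, seed = 13)
  for (g in seq_along(m$params$groups)) {
    for (i in seq_along(m$params$groups[[g]]$blocks)) {
      bl <- m$params$groups[[g]]$blocks[[i]]
      for (nm in names(bl)) bl[[nm]] <- ecglvm:::tree_map(function(x) x * 0,
                                                          bl[[nm]])
      m$params$groups[[g]]$blocks[[i]] <- bl
    }
    m$params$groups[[g]]$emb$w[] <- 0
  }
  sal <- saliency_map(m, tiny_batch(W = 30, seed = 16))
  expect_true(all(sal$values == 0))
})

test_that("importance tables normalize to 100 and aggregate as documented", {
  masks <- build_segment_masks(c(p_onset = 25L, qrs_onset = 100L,
                                 qrs_offset = 150L, t_offset = 325L),
                               W = 350)
  mk_map <- function(values) {
    structure(list(values = values, masks = masks,
                   lead_group_of = stats::setNames(
                     rep(c("limb", "precordial"), each = 6), ecg_leads()),
                   pred = 0),
              class = "saliency_map")
  }
  # uniform saliency: cell share = segment length x 6 leads / (350 x 12)
  uni <- mk_map(matrix(1, 350, 12, dimnames = list(NULL, ecg_leads())))
  tab <- segment_importance(list(uni))
  expect_equal(sum(tab$percentages), 100, tolerance = 1e-6)
  expect_equal(unname(tab$percentages[, "limb"]),
               100 * c(75, 50, 175, 50) * 6 / (350 * 12))
  expect_equal(tab$percentages[, "limb"], tab$percentages[, "precordial"])

  # one-hot: QRS samples of limb leads only
  oh <- matrix(0, 350, 12, dimnames = list(NULL, ecg_leads()))
  oh[masks == "QRS", 1:6] <- 1
  tab_oh <- segment_importance(list(mk_map(oh)))
  expect_equal(unname(tab_oh$percentages["QRS", "limb"]), 100)
  expect_equal(sum(tab_oh$percentages), 100)

  # averaging two identical maps changes nothing
  tab2 <- segment_importance(list(uni, uni))
  expect_equal(tab2$percentages, tab$percentages)
  expect_equal(tab2$n_samples, 2L)

  # all-zero maps are excluded with a warning
  z <- mk_map(matrix(0, 350, 12, dimnames = list(NULL, ecg_leads())))
  expect_warning(tab3 <- segment_importance(list(uni, z)), "all-zero")
  expect_equal(tab3$n_samples, 1L)
  expect_error(suppressWarnings(segment_importance(list(z))), "no usable")
})

test_that("scaling the model output leaves the importance table unchanged", {
  m <- build_model(tiny_spec(), input_length = 30, seed = 21)
  # lift biases so no ReLU path is dead at this random initialization
  m$params$proj$b[] <- 0.3
  for (g in seq_along(m$params$groups)) m$params$groups[[g]]$emb$b[] <- 0.3
  batch <- tiny_batch(W = 30, seed = 22)
  masks <- build_segment_masks(c(p_onset = 2L, qrs_onset = 8L,
                                 qrs_offset = 14L, t_offset = 24L),
                               W = 30)
  t1 <- segment_importance(saliency_map(m, batch, masks = masks))
  mc <- m
  nl <- length(mc$params$reg)
  mc$params$reg[[nl]]$w <- mc$params$reg[[nl]]$w * 7
  mc$params$reg[[nl]]$b <- mc$params$reg[[nl]]$b * 7
  t7 <- segment_importance(saliency_map(mc, batch, masks = masks))
  expect_equal(t7$percentages, t1$percentages, tolerance = 1e-9)
})

test_that("LVM stratification draws seeded tertile samples", {
  rows <- data.frame(lvm_truth = as.numeric(1:300))
  st <- stratify_by_lvm(rows, m = 5, seed = 2)
  expect_true(all(rows$lvm_truth[st$low] <= 100))
  expect_true(all(rows$lvm_truth[st$high] >= 201))
  expect_true(all(rows$lvm_truth[st$middle] > 100 &
                    rows$lvm_truth[st$middle] <= 200))
  expect_identical(st, stratify_by_lvm(rows, m = 5, seed = 2))
  st1 <- stratify_by_lvm(rows, m = 1, seed = 3)
  expect_equal(vapply(st1, length, 0L), c(low = 1L, middle = 1L,
                                          high = 1L))
  expect_error(stratify_by_lvm(rows[1:10, , drop = FALSE], m = 5),
               "too small")
})
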