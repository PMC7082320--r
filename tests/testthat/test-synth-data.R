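test_that("poisson_encode produces calibrated, reproducible Bernoulli trains", {
  expect_true(all(poisson_encode(0, 100, seed = 1) == 0))
  s <- poisson_encode(1, 2000, peak_rate = 0.2, seed = 3)
  p_hat <- mean(s)
  ci <- 3 * sqrt(0.2 * 0.8 / 2000)
  expect_lt(abs(p_hat - 0.2), ci)
  expect_identical(poisson_encode(c(0.5, 1), 50, seed = 7),
                   poisson_encode(c(0.5, 1), 50, seed = 7))
  expect_error(poisson_encode(1.2, 10), "\\[0, 1\\]")
})

test_that("center_crop takes the centred window with even margins", {
  img <- matrix(1:(28 * 28), 28, 28)
  crop <- center_crop(img, 14)
  expect_identical(dim(crop), c(14L, 14L))
  expect_identical(crop, img[8:21, 8:21])
  expect_identical(center_crop(img, 28), img)
  m <- matrix(5, 4, 4)
  expect_true(all(center_crop(m, 2) == 5))
  expect_error(center_crop(m, 6), "exceeds")
})

test_that("make_rate_task builds disjoint-up-to-overlap templates", {
  spec0 <- rate_task_spec(overlap = 0, base_rate = 0, n_per_class = 3,
                          seed = 5)
  task <- make_rate_task(spec0)
  # templates pairwise disjoint at zero overlap
  for (a in 1:2) for (b in (a + 1):3) {
    expect_identical(sum(task$templates[[a]] & task$templates[[b]]), 0L)
  }
  # examples of different classes activate disjoint neuron sets
  active <- lapply(1:3, function(c) {
    which(rowSums(task$examples[[which(task$labels == c)[1]]]) > 0)
  })
  expect_length(intersect(active[[1]], active[[2]]), 0)

  # overlap > 0 shares exactly the common block
  spec2 <- rate_task_spec(overlap = 0.4, seed = 5)
  t2 <- make_rate_task(spec2)$templates
  shared <- which(t2[[1]] & t2[[2]] & t2[[3]])
  expect_length(shared, round(0.4 * (20 %/% 3)))
})

test_that("the dataset is a pure function of its spec", {
  spec <- rate_task_spec(seed = 11)
  expect_identical(make_rate_task(spec), make_rate_task(spec))
})

test_that("the template-matching oracle is exact on fully separated data", {
  spec <- rate_task_spec(overlap = 0, base_rate = 0, n_per_class = 10,
                         seed = 21)
  task <- make_rate_task(spec)
  pred <- vapply(task$examples, template_classify, integer(1),
                 templates = task$templates)
  expect_identical(pred, as.integer(task$labels))
})

test_that("per-neuron empirical rates match the spec within 3-sigma", {
  spec <- rate_task_spec(n_per_class = 30, seed = 13)
  task <- make_rate_task(spec)
  for (c in 1:spec$n_classes) {
    ex <- task$examples[task$labels == c]
    counts <- Reduce(`+`, lapply(ex, rowSums))
    n_obs <- spec$horizon * length(ex)
    rate <- ifelse(task$templates[[c]], spec$peak_rate, spec$base_rate)
    bound <- 3 * sqrt(rate * (1 - rate) / n_obs)
    expect_true(all(abs(counts / n_obs - rate) <= bound + 1e-12))
  }
})

test_that("IDX containers round-trip and reject malformed files", {
  tmp_img <- withr::local_tempfile(fileext = ".idx")
  tmp_lab <- withr::local_tempfile(fileext = ".idx")
  set.seed(2)
  imgs <- array(sample(0:255, 2 * 6 * 6, replace = TRUE), c(2, 6, 6))
  write_idx(imgs, tmp_img)
  write_idx(c(3L, 7L), tmp_lab)
  got <- load_idx_images(tmp_img, tmp_lab)
  expect_identical(got$images, imgs)
  expect_identical(got$labels, c(3L, 7L))

  # bad magic number
  bad <- withr::local_tempfile()
  writeBin(as.raw(c(1, 2, 3, 4, 5, 6, 7, 8)), bad)
  expect_error(read_idx(bad), "magic")

  # truncated data section
  trunc <- withr::local_tempfile()
  full <- readBin(tmp_img, "raw", file.size(tmp_img))
  writeBin(full[1:(length(full) - 10)], trunc)
  expect_error(read_idx(trunc), "truncated")

  # image/label count mismatch
  tmp_lab3 <- withr::local_tempfile()
  write_idx(c(1L, 2L, 3L), tmp_lab3)
  expect_error(load_idx_images(tmp_img, tmp_lab3), "mismatch")
})

test_that("a cropped, Poisson-encoded image feeds the network directly", {
  set.seed(4)
  img <- matrix(runif(28 * 28), 28, 28)
  crop <- center_crop(img, 14)
  spikes <- poisson_encode(as.vector(crop), horizon = 50, seed = 9)
  expect_identical(dim(spikes), c(196L, 50L))
  net <- snn_network(c(196, 10, 2), seed = 1)
  fw <- forward_pass(net, spikes)
  expect_length(fw$counts[[3]], 2)
})
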