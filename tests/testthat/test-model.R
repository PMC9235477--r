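test_that("prediction has the contracted shape and bounded outputs", {
  emb <- hash_embedder(k = 5, dim = 16, seed = 2)
  e1 <- embed_sequence(strrep("ACDEFGHIKL", 4), emb)   # length 40
  e2 <- embed_sequence(strrep("MKVLAW", 10), emb)      # length 60
  m <- seq_model(model_config(projection_dim = 8, hidden_dim = 4,
                              conv_width = 7, pool_width = 9, seed = 1),
                 embed_dim = 16)
  pred <- predict_interaction(m, e1, e2)
  expect_equal(dim(pred$contact_map), c(40, 60))
  expect_true(pred$prob >= 0 && pred$prob <= 1)
  expect_true(all(pred$contact_map >= 0 & pred$contact_map <= 1))
  expect_equal(pred$metadata$shape, c(40, 60))
  expect_equal(pred$metadata$index_base, 1L)
})

test_that("fixed seed gives bit-stable untrained outputs", {
  emb <- hash_embedder(k = 5, dim = 16, seed = 2)
  e1 <- embed_sequence("ACDEFGHIKLMNPQRSTVWY", emb)
  e2 <- embed_sequence("MKVLAWMKVLAW", emb)
  cfg <- model_config(projection_dim = 8, hidden_dim = 4, conv_width = 3,
                      pool_width = 3, seed = 77)
  p1 <- predict_interaction(seq_model(cfg, 16), e1, e2)
  p2 <- predict_interaction(seq_model(cfg, 16), e1, e2)
  expect_identical(p1$prob, p2$prob)
  expect_identical(p1$contact_map, p2$contact_map)
})

test_that("outputs stay in [0,1] across many random untrained models", {
  emb <- hash_embedder(k = 5, dim = 8, seed = 4)
  e1 <- embed_sequence("ACDEFGHIKLMN", emb)
  e2 <- embed_sequence("PQRSTVWYACDE", emb)
  for (s in 1:100) {
    m <- seq_model(model_config(projection_dim = 4, hidden_dim = 2,
                                conv_width = 3, pool_width = 3, seed = s),
                   embed_dim = 8)
    pred <- predict_interaction(m, e1, e2)
    expect_true(pred$prob >= 0 && pred$prob <= 1)
    expect_true(all(pred$contact_map >= 0 & pred$contact_map <= 1))
  }
})

test_that("embedder/model dimension mismatch raises a configuration error", {
  emb <- hash_embedder(dim = 8)
  e1 <- embed_sequence("ACDEF", emb)
  m <- seq_model(model_config(projection_dim = 4, hidden_dim = 2,
                              conv_width = 3, pool_width = 3), embed_dim = 16)
  expect_error(predict_interaction(m, e1, e1), "does not match model",
               class = "glideppi_config_error")
  expect_error(model_config(conv_width = 4), "odd")
})

test_that("contact magnitude is the mean of the map", {
  expect_equal(contact_magnitude(matrix(0, 3, 3)), 0)
  expect_equal(contact_magnitude(matrix(1, 2, 5)), 1)
  expect_equal(contact_magnitude(matrix(c(0.2, 0.6, 0.4, 0.8), 2, 2)), 0.5)
})

test_that("convolution and pooling blocks match naive R references", {
  withr::with_seed(9, {
    n <- 6; m <- 5; h <- 2; k <- 3
    Hmat <- matrix(rnorm(n * m * h), n * m, h)
    K <- array(rnorm(k * k * h), c(k, k, h))
    bk <- 0.3
    got <- glideppi:::cpp_conv2_same(Hmat, K, bk, n, m)
    want <- matrix(bk, n, m)
    for (c in seq_len(h)) {
      Hc <- matrix(Hmat[, c], n, m)
      for (i in 1:n) for (j in 1:m) for (a in 1:k) for (b in 1:k) {
        ii <- i + a - 2; jj <- j + b - 2
        if (ii >= 1 && ii <= n && jj >= 1 && jj <= m)
          want[i, j] <- want[i, j] + K[a, b, c] * Hc[ii, jj]
      }
    }
    expect_equal(got, want, tolerance = 1e-12)

    C <- matrix(runif(n * m), n, m)
    pl <- glideppi:::cpp_maxpool(C, 3)
    expect_equal(dim(pl$P), c(2, 2))
    expect_equal(pl$P[1, 1], max(C[1:3, 1:3]))
    expect_equal(pl$P[2, 2], max(C[4:6, 4:5]))
  })
})

test_that("analytic gradients agree with finite differences", {
  withr::with_seed(1, {
    E1 <- matrix(rnorm(5 * 6), 5, 6)
    E2 <- matrix(rnorm(7 * 6), 7, 6)
  })
  m <- seq_model(model_config(projection_dim = 4, hidden_dim = 3,
                              conv_width = 3, pool_width = 2, seed = 9),
                 embed_dim = 6)
  lcfg <- loss_config(lambda = 0.05, g_p = 0.2)
  lab <- 1; gt <- 0
  p <- m$params
  lossfun <- function(p) {
    fwd <- glideppi:::cpp_model_forward(E1, E2, p$Wp, p$bp, p$Wq, p$bq,
                                        p$K, p$bk, p$gammah, p$kact, 2L)
    total_loss(fwd$yhat, lab, gt, mean(fwd$C), lcfg)
  }
  fwd <- glideppi:::cpp_model_forward(E1, E2, p$Wp, p$bp, p$Wq, p$bq,
                                      p$K, p$bk, p$gammah, p$kact, 2L)
  dy <- glideppi:::loss_dyhat(fwd$yhat, lab, gt, lcfg)
  dCe <- matrix((1 - lcfg$lambda) / length(fwd$C), nrow(fwd$C), ncol(fwd$C))
  g <- glideppi:::cpp_model_backward(fwd, E1, E2, p$Wp, p$Wq, p$K,
                                     p$gammah, p$kact, dy, dCe, 2L)
  eps <- 1e-6
  for (nm in names(p)) {
    ga <- as.numeric(if (nm == "K") array(g[[nm]], dim(p$K)) else g[[nm]])
    idx <- seq_len(min(length(p[[nm]]), 10))
    for (i in idx) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_equal(ga[i], num, tolerance = 1e-4)
    }
  }
})

test_that("checkpoints round-trip the model and metadata", {
  m <- seq_model(model_config(projection_dim = 4, hidden_dim = 2,
                              conv_width = 3, pool_width = 3, seed = 5),
                 embed_dim = 8)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, f, extra = list(note = "x"))
  got <- load_checkpoint(f)
  expect_equal(got$model$params, m$params)
  expect_equal(got$model$config, m$config)
  expect_equal(got$extra$note, "x")
})
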