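test_that("token count formula holds across configurations", {
  expect_equal(token_layout(vit_config())$n_tokens, 789)          # 28^2 + 1 + 4
  cfg64 <- vit_config(image_side = 64, patch_side = 8, embed_dim = 32,
                      depth = 2, heads = 4)
  expect_equal(token_layout(cfg64)$n_tokens, 69)                  # 64 + 1 + 4
  cfg_noreg <- vit_config(image_side = 32, patch_side = 8, embed_dim = 16,
                          depth = 1, heads = 2, n_registers = 0,
                          has_class_token = FALSE)
  expect_equal(token_layout(cfg_noreg)$n_tokens, 16)
  expect_error(vit_config(image_side = 100, patch_side = 14), "divisible")
  expect_error(vit_config(embed_dim = 100, heads = 7), "divisible")
})

test_that("initialisation is seed-deterministic and weight loading is checked", {
  a <- tiny_model(seed = 5); b <- tiny_model(seed = 5)
  expect_identical(a$params, b$params)
  c <- tiny_model(seed = 6)
  expect_false(identical(a$params, c$params))

  bad <- list(patch_W = matrix(0, 3, 3), cls_token = numeric(8))
  err <- tryCatch(build_student(tiny_vit_config(), init_weights = bad),
                  error = function(e) conditionMessage(e))
  expect_match(err, "patch_W")
  expect_match(err, "shape mismatch")

  # loading a model's own weights reproduces it
  re <- build_student(tiny_vit_config(), init_weights = a$params, seed = 99)
  expect_identical(re$params, a$params)
})

test_that("forward pass is deterministic with the contracted output shape", {
  m <- tiny_model()
  x <- tiny_image()
  t1 <- forward_tokens(m, x); t2 <- forward_tokens(m, x)
  expect_identical(t1, t2)
  lay <- token_layout(m$config)
  expect_equal(dim(t1), c(lay$n_tokens, m$config$embed_dim))
  expect_error(forward_tokens(m, array(0, c(8, 8, 3))), "16 x 16")
  # list input maps over images
  lst <- forward_tokens(m, list(a = x, b = x))
  expect_identical(lst$a, lst$b)
})

test_that("corruption replaces exactly the masked patch rows", {
  m <- tiny_model()
  E <- matrix(rnorm(4 * 8), 4, 8)
  tok <- rnorm(8)
  expect_identical(apply_corruption(E, rep(FALSE, 4), tok), E)
  allc <- apply_corruption(E, rep(TRUE, 4), tok)
  expect_true(all(apply(allc, 1, function(r) identical(r, tok))))
  mask <- c(TRUE, FALSE, FALSE, TRUE)
  mixed <- apply_corruption(E, mask, tok)
  changed <- apply(mixed != E, 1, any)
  expect_identical(changed, mask)
  expect_error(apply_corruption(E, c(TRUE, FALSE), tok), "mask length")
})

test_that("zero-scale projector makes the student an exact identity", {
  m <- tiny_model()
  x <- tiny_image()
  expect_identical(unclass(student_output(m, x))[, ],
                   unclass(forward_tokens(m, x))[, ])
  # scale = 1: the residual equals the projector applied to the tokens
  XF <- unclass(forward_tokens(m, x))[, ]
  m1 <- m; m1$params$prj_scale <- rep(1, 8)
  Y <- unclass(student_output(m1, x))[, ]
  p <- m$params
  ln <- fundistill:::layernorm_f(XF, p$prj_ln_g, p$prj_ln_b)
  proj <- fundistill:::gelu(ln$Y %*% p$prj_W1 +
                            rep(p$prj_b1, each = nrow(XF))) %*% p$prj_W2 +
    rep(p$prj_b2, each = nrow(XF))
  expect_equal(Y - XF, proj, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(7)
  m <- tiny_model(seed = 3)
  m$params$prj_scale <- rnorm(8, 0, 0.5)     # exercise the projector path
  x <- tiny_image(seed = 1)
  mask <- c(TRUE, FALSE, TRUE, FALSE)
  lay <- token_layout(m$config)
  Tt <- matrix(rnorm(lay$n_tokens * 8), lay$n_tokens, 8)
  lossfun <- function(mod) {
    mean((fundistill:::vit_forward(mod, x, mask = mask, projector = TRUE)$Y - Tt)^2)
  }
  fw <- fundistill:::vit_forward(m, x, mask = mask, projector = TRUE, cache = TRUE)
  dY <- 2 * (fw$Y - Tt) / length(Tt)
  g <- fundistill:::vit_backward(m, fw$cache, dY)
  eps <- 1e-6
  for (nm in names(g)) {
    p <- m$params[[nm]]
    for (t in 1:2) {
      i <- sample(length(p), 1)
      m2 <- m; m2$params[[nm]][i] <- p[i] + eps
      m3 <- m; m3$params[[nm]][i] <- p[i] - eps
      fd <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
      an <- g[[nm]][i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd), abs(an)), 1e-3)
    }
  }
  # gradient w.r.t. the learnable scale is nonzero on a corrupted batch
  expect_gt(max(abs(g$prj_scale)), 0)
})

test_that("corruption gradients flow to the corruption token, not the patches", {
  m <- tiny_model()
  x <- tiny_image()
  lay <- token_layout(m$config)
  Tt <- matrix(0, lay$n_tokens, 8)
  fw <- fundistill:::vit_forward(m, x, mask = rep(TRUE, 4),
                                 projector = TRUE, cache = TRUE)
  g <- fundistill:::vit_backward(m, fw$cache, 2 * (fw$Y - Tt) / length(Tt))
  expect_true(all(g$patch_W == 0))          # every patch masked: no patch grad
  expect_gt(max(abs(g$corruption_token)), 0)
})

test_that("weight decay mask excludes exactly the bias parameters", {
  m <- tiny_model()
  mask <- weight_decay_mask(m)
  expect_false(any(mask[grepl("_b$|_b1$|_b2$", names(mask))]))
  expect_true(mask[["patch_W"]])
  expect_true(mask[["L01_qkv_W"]])
  expect_true(mask[["pos_embed"]])
})
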