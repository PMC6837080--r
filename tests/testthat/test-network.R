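# helper: kernel sizes of conv nodes reachable in a model
conv_kernels <- function(model) {
  t(vapply(Filter(function(n) n$op == "conv", model$nodes),
           function(n) dim(n$W)[1:2], integer(2)))
}

test_that("forward produces the contracted shapes and pooling arithmetic", {
  cfg <- net_config(encoder_stages = list(c(1, 4), c(1, 6), c(1, 8)),
                    tail_blocks = 1, tail_kernel = 3, decoder_channels = 6,
                    decoder_convs = 1, skip_mode = "fixed", n_classes = 2)
  model <- build_model(cfg, seed = 1)
  x <- array(rnorm(64 * 64 * 3), dim = c(64, 64, 3, 1))
  s <- model_forward(model, x)
  expect_identical(dim(s), c(64L, 64L, 2L, 1L))
  # deepest encoder feature is at 1/4 resolution after two pools
  pools <- which(vapply(model$nodes, function(n) n$op == "pool", TRUE))
  expect_length(pools, 2)
  # fully-convolutional: doubling resolution doubles output resolution
  x2 <- array(rnorm(128 * 128 * 3), dim = c(128, 128, 3, 1))
  expect_identical(dim(model_forward(model, x2))[1:2], c(128L, 128L))
  # non-divisible input is rejected with the divisibility named
  bad <- array(0, dim = c(62, 64, 3, 1))
  expect_error(model_forward(model, bad), "divisible by 4")
})

test_that("extended skip module emits Cin + 12 channels, 12 from the filter bank", {
  for (cin in c(16L, 64L, 128L)) {
    cfg <- net_config(encoder_stages = list(c(1, cin), c(1, 2 * cin)),
                      tail_blocks = 1, tail_kernel = 3,
                      skip_mode = "multiscale", multiscale_kernels = c(3, 5, 7),
                      skip_branch_channels = 12, decoder_channels = 8,
                      decoder_convs = 1, n_classes = 2)
    model <- build_model(cfg, seed = 1)
    concats <- Filter(function(n) n$op == "concat", model$nodes)
    # first concat in graph order is the skip module's (1x1 path, merged bank)
    skip_concat <- concats[[1]]
    expect_identical(model$channels[skip_concat$inputs[1]], cin)       # 1x1 path
    expect_identical(model$channels[skip_concat$inputs[2]], 12L)       # merged bank
    expect_identical(model$channels[skip_concat$id], cin + 12L)
    adds <- Filter(function(n) n$op == "add", model$nodes)
    expect_length(adds, 1)  # one element-wise merge of the three branches
    expect_length(adds[[1]]$inputs, 3)
  }
})

test_that("skip output resolution equals input resolution for any kernel list", {
  cfg <- micro_net_config()
  cfg$multiscale_kernels <- c(1L, 5L, 9L)
  model <- build_model(cfg, seed = 2)
  x <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 2, 1))
  expect_identical(dim(model_forward(model, x))[1:2], c(16L, 16L))
})

test_that("parameter counts match closed-form arithmetic", {
  # a single 3x3 conv, 3 -> 8 channels with bias
  gb <- semgraphics:::new_graph_builder()
  semgraphics:::add_node(gb, list(op = "input", inputs = integer()), 3L)
  semgraphics:::gb_conv(gb, 1L, 3L, 3L, 8L)
  nd <- gb$nodes[[2]]
  expect_identical(length(nd$W) + length(nd$b), 3L * 3L * 3L * 8L + 8L)  # 224

  # separable vs dense tail: 2*k*C^2 vs k^2*C^2 weights per large conv
  base <- list(encoder_stages = list(c(1, 32)), tail_blocks = 1,
               tail_kernel = 15, skip_mode = "none", decoder_channels = 8,
               decoder_convs = 1, n_classes = 2)
  m_sep <- build_model(do.call(net_config, c(base, tail_separable = TRUE)), seed = 1)
  m_dense <- build_model(do.call(net_config, c(base, tail_separable = FALSE)), seed = 1)
  tail_w <- function(m) {
    ks <- conv_kernels(m)
    big <- which(ks[, 1] > 3 | ks[, 2] > 3)
    convs <- Filter(function(n) n$op == "conv", m$nodes)
    sum(vapply(convs[big], function(n) length(n$W), 0))
  }
  expect_identical(tail_w(m_sep), 2 * 15 * 32 * 32)
  expect_identical(tail_w(m_dense), 15 * 15 * 32 * 32)
  expect_lt(count_parameters(m_sep), count_parameters(m_dense))
  # identical output shapes either way
  x <- array(rnorm(32 * 32 * 3), dim = c(32, 32, 3, 1))
  expect_identical(dim(model_forward(m_sep, x)), dim(model_forward(m_dense, x)))
  # count is a pure weight count: invariant across forward passes
  n0 <- count_parameters(m_sep)
  invisible(model_forward(m_sep, x))
  expect_identical(count_parameters(m_sep), n0)
})

test_that("two large-kernel tail blocks are present by default", {
  cfg <- tiny_net_config()
  expect_identical(cfg$tail_blocks, 2L)
  model <- build_model(cfg, seed = 1)
  ks <- conv_kernels(model)
  # separable pairs: each tail block contributes a (7,1) and a (1,7) conv;
  # skip branches contribute (k,1)/(1,k) for k in 3,5,7 at one level
  expect_identical(sum(ks[, 1] == 7 & ks[, 2] == 1), 2L + 1L)
  expect_identical(sum(ks[, 1] == 1 & ks[, 2] == 7), 2L + 1L)
})

test_that("all ablation variants build and run from configuration alone", {
  base <- list(encoder_stages = list(c(1, 6), c(1, 8)), decoder_channels = 6,
               decoder_convs = 1, n_classes = 2)
  variants <- list(
    unet = c(base, list(skip_mode = "fixed", tail_blocks = 0)),
    unet_wc = c(base, list(skip_mode = "fixed", tail_blocks = 2, tail_kernel = 7)),
    single = c(base, list(skip_mode = "single_scale", single_scale_k = 7,
                          tail_blocks = 2, tail_kernel = 7)),
    esnet = c(base, list(skip_mode = "multiscale", multiscale_kernels = c(3, 5, 7),
                         tail_blocks = 2, tail_kernel = 7)),
    noskip = c(base, list(skip_mode = "none", tail_blocks = 1, tail_kernel = 7)))
  x <- array(rnorm(16 * 16 * 3), dim = c(16, 16, 3, 1))
  for (nm in names(variants)) {
    model <- build_model(do.call(net_config, variants[[nm]]), seed = 3)
    s <- model_forward(model, x)
    expect_identical(dim(s), c(16L, 16L, 2L, 1L), label = nm)
    expect_true(all(is.finite(s)), label = nm)
  }
  # decoder-side concatenated channels = decoder + Cin (+12 for multiscale)
  m_fix <- build_model(do.call(net_config, variants$unet), seed = 1)
  m_ms <- build_model(do.call(net_config, variants$esnet), seed = 1)
  dec_concat <- function(m) {
    cc <- Filter(function(n) n$op == "concat", m$nodes)
    model_ch <- m$channels[cc[[length(cc)]]$id]
    model_ch
  }
  expect_identical(dec_concat(m_fix), 8L + 6L)        # upsampled tail + fixed skip
  expect_identical(dec_concat(m_ms), 8L + 6L + 12L)   # + learned 12 extra
})

test_that("forward is sane: finite on zeros, batch-independent in eval mode", {
  model <- build_model(micro_net_config(), seed = 5)
  z <- array(0, dim = c(16, 16, 2, 1))
  expect_true(all(is.finite(model_forward(model, z))))
  set.seed(8)
  img <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 2))
  one <- model_forward(model, array(img, dim = c(16, 16, 2, 1)))
  two <- model_forward(model, array(rep(img, 2), dim = c(16, 16, 2, 2)))
  expect_equal(one[, , , 1], two[, , , 1], tolerance = 1e-12)
  expect_equal(two[, , , 1], two[, , , 2], tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  model <- build_model(micro_net_config(), seed = 42)
  set.seed(7)
  # perturb all parameters away from 0 to break exact ReLU/pool ties
  params <- semgraphics:::model_params(model)
  params <- lapply(params, function(p) p + rnorm(length(p), 0, 0.05))
  model <- semgraphics:::model_set_params(model, params)
  x <- array(rnorm(8 * 8 * 2 * 2), dim = c(8, 8, 2, 2))
  y <- array(sample(0:1, 8 * 8 * 2, TRUE), dim = c(8, 8, 2))
  wts <- c(0.7, 1.9)
  lossfun <- function(m)
    weighted_cross_entropy(model_forward(m, x, training = TRUE), y, wts)
  fw <- model_forward(model, x, training = TRUE, keep_cache = TRUE)
  lo <- weighted_cross_entropy(fw$scores, y, wts, grad = TRUE)
  bw <- semgraphics:::model_backward(model, fw$cache, lo$grad)
  # every trainable weight has a defined, finite gradient
  expect_setequal(names(bw$param_grads), names(params))
  for (g in bw$param_grads) expect_true(all(is.finite(g)))
  eps <- 1e-5
  for (k in names(params)) {
    i <- sample(length(params[[k]]), 1)
    p2 <- params; p2[[k]][i] <- p2[[k]][i] + eps
    lp <- lossfun(semgraphics:::model_set_params(model, p2))
    p2[[k]][i] <- p2[[k]][i] - 2 * eps
    lm <- lossfun(semgraphics:::model_set_params(model, p2))
    num <- (lp - lm) / (2 * eps)
    ana <- bw$param_grads[[k]][i]
    expect_lt(abs(num - ana), 1e-6 + 1e-4 * (abs(num) + abs(ana)))
  }
})

test_that("checkpoints are self-describing and round-trip exactly", {
  model <- build_model(micro_net_config(), seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  m2 <- load_checkpoint(f)
  set.seed(1)
  x <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2, 1))
  expect_equal(model_forward(m2, x), model_forward(model, x), tolerance = 1e-12)
  expect_identical(m2$config, model$config)
})
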