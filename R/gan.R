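# Unpaired image-to-image realism transform, CycleGAN-style: two U-Net
# generators and two patch discriminators trained with least-squares
# adversarial, cycle-consistency and identity losses. Applied to rendered
# pairs it replaces the pseudo image while passing labels through
# bit-exactly.

#' CycleGAN configuration
#'
#' Canonical published defaults: cycle weight `lambda = 10`, identity
#' weight `0.5 * lambda`, least-squares adversarial loss, patch
#' discriminator, Adam at `lr = 2e-4` with linear decay over the second
#' half of training, 200 epochs with checkpoints every 5. The generators
#' are U-Nets; `levels = 8` requires images of at least 256 x 256, and
#' `image_size` must be divisible by `2^levels`.
#'
#' @param image_size square image side in pixels.
#' @param levels generator down-sampling levels (8 at full scale; reduce
#'   for smaller images).
#' @param base generator base channels.
#' @param disc_base,disc_down patch-discriminator width and depth.
#' @param lambda_cycle cycle-consistency weight.
#' @param identity_frac identity weight as a fraction of `lambda_cycle`.
#' @param lr initial Adam learning rate.
#' @param epochs training epochs.
#' @param checkpoint_every save a generator checkpoint every this many
#'   epochs.
#' @param seed RNG seed.
#' @return a `cyclegan_config` list.
#' @export
cyclegan_config <- function(image_size = 256L, levels = 8L, base = 8L,
                            disc_base = 8L, disc_down = 2L,
                            lambda_cycle = 10, identity_frac = 0.5,
                            lr = 2e-4, epochs = 200L, checkpoint_every = 5L,
                            seed = 0L) {
  if (epochs < 0) stop("epochs must be >= 0 (0 = no further training)")
  if (image_size %% 2^levels != 0)
    stop("image_size ", image_size, " not divisible by 2^", levels,
         " (down-sampling levels)")
  structure(as.list(environment()), class = "cyclegan_config")
}

read_image_dir <- function(dir, image_size) {
  if (is.character(dir)) {
    files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no images in directory: ", dir)
    imgs <- lapply(files, function(f) {
      im <- png::readPNG(f)
      if (length(dim(im)) == 3) im <- im[, , 1]
      if (nrow(im) != image_size || ncol(im) != image_size)
        stop("image size mismatch in ", f, ": ", nrow(im), "x", ncol(im),
             " (expected ", image_size, ")")
      im
    })
    return(imgs)
  }
  if (!length(dir)) stop("empty image set")
  for (i in seq_along(dir))
    if (nrow(dir[[i]]) != image_size || ncol(dir[[i]]) != image_size)
      stop("image size mismatch at index ", i)
  dir
}

# one optimisation step on image pair (a, b); returns updated nets/states
# and the step's loss components
cyclegan_step <- function(S, a, b, lam, lam_idt, lr) {
  # generator pass ------------------------------------------------------
  f1 <- unet_forward(S$g_ab, a, want_cache = TRUE)   # fake_b
  f2 <- unet_forward(S$g_ba, f1$out, want_cache = TRUE)  # rec_a
  f3 <- unet_forward(S$g_ba, b, want_cache = TRUE)   # fake_a
  f4 <- unet_forward(S$g_ab, f3$out, want_cache = TRUE)  # rec_b
  f5 <- unet_forward(S$g_ab, b, want_cache = TRUE)   # idt_b
  f6 <- unet_forward(S$g_ba, a, want_cache = TRUE)   # idt_a
  d1 <- disc_forward(S$d_b, f1$out, want_cache = TRUE)
  d2 <- disc_forward(S$d_a, f3$out, want_cache = TRUE)
  adv1 <- mse_loss(d1$out, 1)
  adv2 <- mse_loss(d2$out, 1)
  cyc1 <- l1_loss(f2$out, a)
  cyc2 <- l1_loss(f4$out, b)
  idt1 <- l1_loss(f5$out, b)
  idt2 <- l1_loss(f6$out, a)

  d_fake_b <- disc_backward(S$d_b, d1$caches, adv1$da)$dx
  bk2 <- unet_backward(S$g_ba, f2$cache, lam * cyc1$da)
  g_ab1 <- unet_backward(S$g_ab, f1$cache, d_fake_b + bk2$dx)$grads
  d_fake_a <- disc_backward(S$d_a, d2$caches, adv2$da)$dx
  bk4 <- unet_backward(S$g_ab, f4$cache, lam * cyc2$da)
  g_ba1 <- unet_backward(S$g_ba, f3$cache, d_fake_a + bk4$dx)$grads
  g_ab2 <- unet_backward(S$g_ab, f5$cache, lam_idt * idt1$da)$grads
  g_ba2 <- unet_backward(S$g_ba, f6$cache, lam_idt * idt2$da)$grads

  r <- adam_step(S$g_ab, grads_add(grads_add(g_ab1, bk4$grads), g_ab2),
                 S$st_g_ab, lr = lr)
  S$g_ab <- r$net; S$st_g_ab <- r$state
  r <- adam_step(S$g_ba, grads_add(grads_add(bk2$grads, g_ba1), g_ba2),
                 S$st_g_ba, lr = lr)
  S$g_ba <- r$net; S$st_g_ba <- r$state

  # discriminator pass (fakes detached) ---------------------------------
  upd_d <- function(dnet, dst, real, fake) {
    r1 <- disc_forward(dnet, real, want_cache = TRUE)
    l1d <- mse_loss(r1$out, 1)
    g1 <- disc_backward(dnet, r1$caches, grads_scale(l1d$da, 0.5))$grads
    r2 <- disc_forward(dnet, fake, want_cache = TRUE)
    l2d <- mse_loss(r2$out, 0)
    g2 <- disc_backward(dnet, r2$caches, grads_scale(l2d$da, 0.5))$grads
    r <- adam_step(dnet, grads_add(g1, g2), dst, lr = lr)
    list(net = r$net, st = r$state, loss = (l1d$loss + l2d$loss) / 2)
  }
  rb <- upd_d(S$d_b, S$st_d_b, b, f1$out)
  S$d_b <- rb$net; S$st_d_b <- rb$st
  ra <- upd_d(S$d_a, S$st_d_a, a, f3$out)
  S$d_a <- ra$net; S$st_d_a <- ra$st

  S$step_loss <- c(g_adv = adv1$loss + adv2$loss,
                   cycle = cyc1$loss + cyc2$loss,
                   identity = idt1$loss + idt2$loss,
                   d = ra$loss + rb$loss)
  S
}

#' Train the pseudo-to-real transform
#'
#' Trains the CycleGAN on an unpaired pseudo-image domain A and real-image
#' domain B; the A-to-B generator is the transform of interest. Checkpoints
#' of it are stored every `checkpoint_every` epochs, the learning rate
#' decays linearly to zero over the second half of training, and the
#' training log records per-epoch mean losses.
#'
#' @param pseudo domain-A images: a directory of PNGs or a list of H x W
#'   matrices in `[0,1]`.
#' @param real domain-B images, same formats.
#' @param config a [cyclegan_config()].
#' @param init optional donor `trained_transform` for warm starts (see
#'   [init_from()]).
#' @return a `trained_transform`: `gen_ab`, `gen_ba`, `checkpoints`
#'   (list of `list(epoch, gen_ab)`), `log` (one row per epoch), `config`.
#' @export
train_cyclegan <- function(pseudo, real, config = cyclegan_config(),
                           init = NULL) {
  A <- read_image_dir(pseudo, config$image_size)
  B <- read_image_dir(real, config$image_size)
  set.seed(as.integer(config$seed))
  if (is.null(init)) {
    # generators carry instance normalisation, as in the reference
    # CycleGAN generator architecture
    S <- list(g_ab = unet_new(1L, 1L, config$levels, config$base,
                              final = "sigmoid", norm = TRUE),
              g_ba = unet_new(1L, 1L, config$levels, config$base,
                              final = "sigmoid", norm = TRUE),
              d_a = disc_new(1L, config$disc_base, config$disc_down),
              d_b = disc_new(1L, config$disc_base, config$disc_down))
  } else {
    if (init$config$levels != config$levels || init$config$base != config$base)
      stop("architecture mismatch: donor transform has levels/base ",
           init$config$levels, "/", init$config$base, ", config asks ",
           config$levels, "/", config$base)
    S <- init$state
  }
  S$st_g_ab <- adam_state(); S$st_g_ba <- adam_state()
  S$st_d_a <- adam_state(); S$st_d_b <- adam_state()
  lam <- config$lambda_cycle
  lam_idt <- config$identity_frac * lam
  n <- min(length(A), length(B))
  log <- NULL
  checkpoints <- list()
  to_arr <- function(m) array(m, c(nrow(m), ncol(m), 1L))
  for (e in seq_len(config$epochs)) {
    lr_e <- config$lr * min(1, 2 * (1 - (e - 1) / config$epochs))
    ia <- sample(length(A), n)
    ib <- sample(length(B), n)
    acc <- c(g_adv = 0, cycle = 0, identity = 0, d = 0)
    for (i in seq_len(n)) {
      S <- cyclegan_step(S, to_arr(A[[ia[i]]]), to_arr(B[[ib[i]]]),
                         lam, lam_idt, lr_e)
      acc <- acc + S$step_loss
    }
    row <- as.data.frame(as.list(acc / n))
    row$epoch <- e
    log <- rbind(log, row)
    if (e %% config$checkpoint_every == 0)
      checkpoints[[length(checkpoints) + 1L]] <- list(epoch = e, gen_ab = S$g_ab)
  }
  if (!is.null(log) &&
      any(!is.finite(as.matrix(log[, c("g_adv", "cycle", "identity", "d")]))))
    warning("non-finite losses recorded during training")
  structure(list(gen_ab = S$g_ab, gen_ba = S$g_ba,
                 state = S[c("g_ab", "g_ba", "d_a", "d_b")],
                 checkpoints = checkpoints, log = log, config = config),
            class = "trained_transform")
}

#' Warm-start configuration from a trained transform
#'
#' Returns a config + donor bundle for [train_cyclegan()]: the new run
#' starts from the donor's weights (all four networks) and typically trains
#' for fewer epochs (e.g. 100 when adapting an existing transform to a new
#' dataset).
#'
#' @param previous a `trained_transform`.
#' @param epochs epochs for the continuation (default 100).
#' @param ... overrides passed to [cyclegan_config()].
#' @return list with `config` and `init` ready for
#'   `train_cyclegan(config = , init = )`.
#' @export
init_from <- function(previous, epochs = 100L, ...) {
  over <- list(...)
  base <- previous$config
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base$epochs <- as.integer(epochs)
  cfg <- do.call(cyclegan_config, base[setdiff(names(base), character(0))])
  list(config = cfg, init = previous)
}

#' Apply a trained transform to rendered pairs
#'
#' Replaces each pseudo image by the generator output (re-masked to the
#' cone); the label raster is copied bit-identically, so pairing is
#' preserved exactly.
#'
#' @param transform a `trained_transform`, or a single generator
#'   checkpoint entry from its `checkpoints`.
#' @param pairs list of `pseudo_pair`.
#' @param epoch optional checkpoint epoch to use instead of the final
#'   generator.
#' @return list of transformed `pseudo_pair` (provenance annotated).
#' @export
transform_dataset <- function(transform, pairs, epoch = NULL) {
  gen <- if (is.null(epoch)) {
    transform$gen_ab
  } else {
    hit <- Filter(function(ck) ck$epoch == epoch, transform$checkpoints)
    if (!length(hit)) stop("no checkpoint at epoch ", epoch)
    hit[[1]]$gen_ab
  }
  lapply(pairs, function(p) {
    H <- nrow(p$image); W <- ncol(p$image)
    out <- unet_forward(gen, array(p$image, c(H, W, 1L)))
    img <- matrix(out, H, W)
    img[!cone_mask(p$cone)] <- 0
    p$image <- matrix(pmin(1, pmax(0, img)), H, W)
    p$provenance$transformed <- TRUE
    p
  })
}
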