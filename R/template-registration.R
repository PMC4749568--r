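#' Image stacks, transforms and similarity
#'
#' Stacks are plain 3D numeric arrays (x, y, z voxel order, unit spacing
#' unless noted). A transform maps an output voxel coordinate `x` (1-based)
#' to the source sampling coordinate
#' `T(x) = c + A (x - c) + t + disp(x)`,
#' where `c` is the grid centre, `A` a 3x3 matrix, `t` a translation, and
#' `disp` an optional smooth displacement field interpolated from a coarse
#' control-point grid. Resampling is trilinear with zero fill outside the
#' grid.
#'
#' @name stack-transforms
NULL

make_transform <- function(A = diag(3), t = c(0, 0, 0), disp = NULL,
                           control_dim = c(4, 4, 2),
                           kind = if (is.null(disp)) "affine" else "affdef") {
  if (abs(det(A)) < 1e-12) {
    abort("affine part must be invertible", class = "sigold_parameter_error")
  }
  structure(list(kind = kind, A = A, t = as.numeric(t), disp = disp,
                 control_dim = as.integer(control_dim)),
            class = "sigold_transform")
}

identity_transform <- function() make_transform()

# full (or strided) voxel coordinate grid as an N x 3 matrix
grid_coords <- function(d, stride = c(1, 1, 1)) {
  xs <- seq(1, d[1], by = stride[1])
  ys <- seq(1, d[2], by = stride[2])
  zs <- seq(1, d[3], by = stride[3])
  cbind(rep(xs, times = length(ys) * length(zs)),
        rep(rep(ys, each = length(xs)), times = length(zs)),
        rep(zs, each = length(xs) * length(ys)))
}

# trilinear interpolation of `arr` at coordinates P (N x 3); 0 outside
sample_trilinear <- function(arr, P) {
  d <- dim(arr)
  out <- numeric(nrow(P))
  i0 <- floor(P)
  f <- P - i0
  for (k in 1:3) {             # border voxels: fold x0 == d onto the last cell
    at <- i0[, k] == d[k] & f[, k] == 0
    i0[at, k] <- d[k] - 1
    f[at, k] <- 1
  }
  ok <- i0[, 1] >= 1 & i0[, 1] < d[1] &
        i0[, 2] >= 1 & i0[, 2] < d[2] &
        i0[, 3] >= 1 & i0[, 3] < d[3]
  if (!any(ok)) return(out)
  x0 <- i0[ok, 1]; y0 <- i0[ok, 2]; z0 <- i0[ok, 3]
  fx <- f[ok, 1]; fy <- f[ok, 2]; fz <- f[ok, 3]
  v <- as.vector(arr)
  at <- function(ix, iy, iz) v[ix + (iy - 1) * d[1] + (iz - 1) * d[1] * d[2]]
  out[ok] <-
    (1 - fx) * (1 - fy) * (1 - fz) * at(x0,     y0,     z0) +
    fx       * (1 - fy) * (1 - fz) * at(x0 + 1, y0,     z0) +
    (1 - fx) * fy       * (1 - fz) * at(x0,     y0 + 1, z0) +
    fx       * fy       * (1 - fz) * at(x0 + 1, y0 + 1, z0) +
    (1 - fx) * (1 - fy) * fz       * at(x0,     y0,     z0 + 1) +
    fx       * (1 - fy) * fz       * at(x0 + 1, y0,     z0 + 1) +
    (1 - fx) * fy       * fz       * at(x0,     y0 + 1, z0 + 1) +
    fx       * fy       * fz       * at(x0 + 1, y0 + 1, z0 + 1)
  out
}

# trilinear basis weights of the control-point grid at coordinates P;
# control points span [1, dim] inclusive in each axis
ctrl_basis <- function(P, d, control_dim) {
  n <- control_dim
  U <- sapply(1:3, function(k) {
    if (n[k] == 1) rep(1, nrow(P))
    else (P[, k] - 1) / (d[k] - 1) * (n[k] - 1) + 1
  })
  U <- pmin(pmax(U, 1), matrix(n, nrow(P), 3, byrow = TRUE))
  i0 <- floor(U)
  for (k in 1:3) i0[i0[, k] == n[k], k] <- max(n[k] - 1, 1)
  f <- U - i0
  B <- matrix(0, nrow(P), prod(n))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ix <- pmin(i0[, 1] + dx, n[1])
    iy <- pmin(i0[, 2] + dy, n[2])
    iz <- pmin(i0[, 3] + dz, n[3])
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    col <- ix + (iy - 1) * n[1] + (iz - 1) * n[1] * n[2]
    B[cbind(seq_len(nrow(P)), col)] <- B[cbind(seq_len(nrow(P)), col)] + w
  }
  B
}

# apply a transform to points: source coordinates for each output point
transform_points <- function(P, tf, d, B = NULL) {
  ctr <- (d + 1) / 2
  src <- sweep(sweep(P, 2, ctr) %*% t(tf$A), 2, ctr + tf$t, `+`)
  if (!is.null(tf$disp)) {
    if (is.null(B)) B <- ctrl_basis(P, d, tf$control_dim)
    src <- src + B %*% tf$disp
  }
  src
}

#' Resample a stack under a transform
#'
#' @param arr 3D array (the moving image).
#' @param tf A transform from [register()] / the synthetic renderer.
#' @param d Output grid dimensions (default `dim(arr)`).
#' @return Warped 3D array: `out[x] = arr[T(x)]` by trilinear
#'   interpolation.
#' @export
warp_stack <- function(arr, tf, d = dim(arr)) {
  P <- grid_coords(d)
  array(sample_trilinear(arr, transform_points(P, tf, d)), dim = d)
}

#' @rdname warp_stack
#' @param iters Fixed-point iterations used to invert the (near-identity)
#'   transform pointwise.
#' @export
warp_stack_inverse <- function(arr, tf, d = dim(arr), iters = 10) {
  P <- grid_coords(d)
  B <- if (!is.null(tf$disp)) ctrl_basis(P, d, tf$control_dim)
  X <- P
  for (i in seq_len(iters)) {
    X <- X + (P - transform_points(X, tf, d,
                                   B = if (!is.null(tf$disp))
                                     ctrl_basis(X, d, tf$control_dim)))
  }
  array(sample_trilinear(arr, X), dim = d)
}

#' Normalised cross-correlation similarity
#'
#' Pearson correlation of voxel intensities; 1 for identical stacks. Used
#' as the iteration metric when ranking registered stacks during template
#' construction.
#'
#' @param a,b 3D arrays of equal dimension.
#' @return Scalar in \[-1, 1\].
#' @export
similarity_score <- function(a, b) {
  va <- as.vector(a); vb <- as.vector(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    return(if (isTRUE(all.equal(va, vb))) 1 else 0)
  }
  stats::cor(va, vb)
}

center_of_mass <- function(arr) {
  w <- pmax(as.vector(arr), 0)
  if (sum(w) == 0) {
    abort("all-zero stack has no center of mass",
          class = "sigold_degenerate_error")
  }
  P <- grid_coords(dim(arr))
  colSums(P * w) / sum(w)
}

#' Orient stacks and align their centres of mass
#'
#' Translates each stack so its intensity centre of mass sits at the grid
#' centre (sub-voxel, trilinear). With `orient = TRUE` the in-plane
#' principal axis of the intensity distribution is additionally rotated
#' onto the x axis.
#'
#' @param stacks A 3D array or (named) list of 3D arrays.
#' @param orient Apply principal-axis orientation (default `FALSE`).
#' @return Stacks of the same shape as the input.
#' @export
orient_and_center <- function(stacks, orient = FALSE) {
  one <- function(arr) {
    d <- dim(arr)
    ctr <- (d + 1) / 2
    com <- center_of_mass(arr)
    A <- diag(3)
    if (orient) {
      P <- grid_coords(d)
      w <- pmax(as.vector(arr), 0)
      Pc <- sweep(P[, 1:2], 2, com[1:2])
      C <- crossprod(Pc * sqrt(w / sum(w)))
      e <- eigen(C, symmetric = TRUE)$vectors[, 1]
      th <- atan2(e[2], e[1])
      R <- diag(3)
      R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      A <- R
    }
    # choose t so the (rotated) center of mass lands on the grid center
    t <- as.vector(A %*% (com - ctr))
    warp_stack(arr, make_transform(A = A, t = t))
  }
  if (is.list(stacks)) lapply(stacks, one) else one(stacks)
}

# rigid/affine parameter vectors <-> transforms
params_to_transform <- function(p, kind) {
  if (kind == "rigid") {
    t <- p[1:3]; r <- p[4:6]
    cx <- cos(r); sx <- sin(r)
    Rx <- rbind(c(1, 0, 0), c(0, cx[1], -sx[1]), c(0, sx[1], cx[1]))
    Ry <- rbind(c(cx[2], 0, sx[2]), c(0, 1, 0), c(-sx[2], 0, cx[2]))
    Rz <- rbind(c(cx[3], -sx[3], 0), c(sx[3], cx[3], 0), c(0, 0, 1))
    make_transform(A = Rz %*% Ry %*% Rx, t = t, kind = "rigid")
  } else {
    make_transform(A = diag(3) + matrix(p[4:12], 3, 3), t = p[1:3])
  }
}

#' Register a moving stack to a reference
#'
#' Finds the transform of the requested model class that maximises the
#' normalised cross-correlation between the warped moving stack and the
#' reference. Rigid and affine parameters are optimised by Nelder-Mead
#' from the identity; the deformable stage (`"affdef"`) then runs a greedy
#' block-coordinate descent over the control-point displacements, so its
#' score never falls below the affine-only score. If the optimizer does
#' not formally converge the best transform found so far is returned with
#' `converged = FALSE`.
#'
#' @param moving,reference 3D arrays of identical dimension.
#' @param kind `"rigid"`, `"affine"` or `"affdef"`.
#' @param maxit Nelder-Mead iteration budget.
#' @param stride Integer subsampling stride (x, y) of the voxel grid used
#'   during optimisation; the returned score is always computed on the
#'   full grid.
#' @param control_dim Control-point grid of the deformable part.
#' @param sweeps Coordinate-descent sweeps of the deformable stage.
#' @param step_vox Initial deformable probe step (voxels); halved each
#'   sweep.
#' @param restarts Maximum Nelder-Mead restarts from the incumbent
#'   optimum; restarting stops once the similarity gain falls below 1e-4.
#' @return List with `transform`, `score` (full-grid similarity),
#'   `converged`.
#' @export
register <- function(moving, reference, kind = c("affine", "rigid",
                                                 "affdef"),
                     maxit = 250, stride = 2, control_dim = c(4, 4, 2),
                     sweeps = 2, step_vox = 0.75, restarts = 3) {
  kind <- match.arg(kind)
  stopifnot(all(dim(moving) == dim(reference)))
  d <- dim(moving)
  P <- grid_coords(d, stride = c(stride, stride, 1))
  ref_sub <- sample_trilinear(reference, P)
  base_kind <- if (kind == "rigid") "rigid" else "affine"
  np <- if (base_kind == "rigid") 6 else 12
  neg_ncc <- function(p) {
    tf <- params_to_transform(p, base_kind)
    w <- sample_trilinear(moving, transform_points(P, tf, d))
    if (stats::sd(w) == 0) return(0)
    -stats::cor(w, ref_sub)
  }
  p0 <- rep(0, np)
  f0 <- neg_ncc(p0)
  ps <- if (base_kind == "rigid") c(rep(1, 3), rep(0.05, 3))
        else c(rep(1, 3), rep(0.05, 9))
  # iterated Nelder-Mead: restart from the incumbent until the gain stalls
  best_p <- p0
  best_f <- f0
  converged <- TRUE
  for (rs in seq_len(restarts)) {
    opt <- stats::optim(best_p, neg_ncc, method = "Nelder-Mead",
                        control = list(maxit = maxit, parscale = ps,
                                       reltol = 1e-9))
    converged <- opt$convergence == 0
    if (opt$value < best_f - 1e-12) {
      gain <- best_f - opt$value
      best_p <- opt$par
      best_f <- opt$value
      if (gain < 1e-4) break
    } else {
      break
    }
  }
  tf <- params_to_transform(best_p, base_kind)
  if (kind == "affdef") {
    B <- ctrl_basis(P, d, control_dim)
    ctr <- (d + 1) / 2
    P_aff <- sweep(sweep(P, 2, ctr) %*% t(tf$A), 2, ctr + tf$t, `+`)
    D <- matrix(0, prod(control_dim), 3)
    eval_D <- function(D) {
      w <- sample_trilinear(moving, P_aff + B %*% D)
      if (stats::sd(w) == 0) return(0)
      -stats::cor(w, ref_sub)
    }
    cur <- eval_D(D)
    step <- step_vox
    for (sw in seq_len(sweeps)) {
      for (j in seq_len(nrow(D))) for (a in 1:3) for (s in c(-step, step)) {
        Dc <- D
        Dc[j, a] <- Dc[j, a] + s
        v <- eval_D(Dc)
        if (v < cur - 1e-12) {
          D <- Dc
          cur <- v
        }
      }
      step <- step / 2
    }
    tf <- make_transform(A = tf$A, t = tf$t, disp = D,
                         control_dim = control_dim)
  }
  full <- warp_stack(moving, tf)
  list(transform = tf, score = similarity_score(full, reference),
       converged = converged)
}

#' Build an unbiased average template by iterative registration
#'
#' Implements the groupwise scheme used for whole-body reference
#' templates: all stacks are centred (and optionally oriented) and naively
#' averaged; then, per stage, every *original* oriented stack is
#' registered to the current average, the `k_keep` registered stacks most
#' similar to it (by the similarity metric) are averaged into the next
#' template. The default staging is one affine round followed by two
#' affine+deformable rounds, after which the average is taken as the final
#' unbiased template. Registration always restarts from the original
#' oriented stacks, never from previously warped copies; averaging and
#' ranking are order-invariant (ties broken by stack name), so a permuted
#' input yields an identical template.
#'
#' @param stacks Named list of 3D arrays (>= `k_keep`); unnamed lists get
#'   positional names.
#' @param k_keep Number of most-similar stacks averaged each stage
#'   (default 24, of a cohort of 36).
#' @param stages Character vector of per-stage models, each `"rigid"`,
#'   `"affine"` or `"affdef"`.
#' @param orient Passed to [orient_and_center()].
#' @inheritParams register
#' @return A `sigold_template`: list with `template` (3D array),
#'   `history` (tibble: stage, stack, score, rank, kept), `transforms`
#'   (last-stage transforms) and `stages`.
#' @export
build_template <- function(stacks, k_keep = 24,
                           stages = c("affine", "affdef", "affdef"),
                           orient = FALSE, maxit = 250, stride = 2,
                           control_dim = c(4, 4, 2), sweeps = 2,
                           restarts = 2) {
  if (length(stacks) < k_keep) {
    abort(sprintf("k_keep (%d) exceeds the number of stacks (%d)",
                  k_keep, length(stacks)),
          class = "sigold_parameter_error")
  }
  if (is.null(names(stacks)) || any(names(stacks) == "")) {
    names(stacks) <- sprintf("stack%02d", seq_along(stacks))
  }
  oriented <- orient_and_center(stacks, orient = orient)
  nm <- sort(names(oriented))
  avg <- Reduce(`+`, oriented[nm]) / length(oriented)
  history <- list()
  transforms <- NULL
  for (st in seq_along(stages)) {
    regs <- lapply(oriented[nm], register, reference = avg,
                   kind = stages[st], maxit = maxit, stride = stride,
                   control_dim = control_dim, sweeps = sweeps,
                   restarts = restarts)
    scores <- vapply(regs, `[[`, numeric(1), "score")
    ord <- nm[order(-scores, nm)]
    kept <- ord[seq_len(k_keep)]
    warped <- lapply(kept, function(n) {
      warp_stack(oriented[[n]], regs[[n]]$transform)
    })
    avg <- Reduce(`+`, warped) / k_keep
    history[[st]] <- tibble(
      stage = st, model = stages[st], stack = ord,
      score = unname(scores[ord]), rank = seq_along(ord),
      kept = ord %in% kept)
    transforms <- lapply(regs, `[[`, "transform")
  }
  structure(list(template = avg, history = bind_rows(history),
                 transforms = transforms, stages = stages,
                 k_keep = k_keep),
            class = "sigold_template")
}

#' @export
print.sigold_template <- function(x, ...) {
  ms <- x$history |>
    group_by(.data$stage) |>
    summarise(mean_score = mean(.data$score[.data$kept]), .groups = "drop")
  cat(sprintf("<sigold_template: %s; keep %d; mean kept similarity by stage: %s>\n",
              paste(x$stages, collapse = " -> "), x$k_keep,
              paste(sprintf("%.3f", ms$mean_score), collapse = ", ")))
  invisible(x)
}

#' Render synthetic immunofluorescence-like stacks
#'
#' Generates a shared smooth ground-truth intensity pattern (a mixture of
#' 3D Gaussian blobs) and renders each stack by applying a random small
#' affine transform plus a smooth low-frequency deformation, then adding
#' Gaussian noise. The ground-truth pattern and per-stack transforms are
#' retained so registration and template construction can be validated
#' against truth.
#'
#' @param n_stacks Number of stacks (>= 1); a full cohort is 36.
#' @param d Stack dimensions in voxels (default 64 x 64 x 8).
#' @param n_blobs Number of Gaussian blobs in the truth pattern.
#' @param noise_sd Additive Gaussian noise SD (intensity units; truth has
#'   peak ~1).
#' @param max_shift_vox,max_angle_deg,max_log_scale Ranges of the random
#'   affine (in-plane rotation and isotropic scale, xyz translation).
#' @param deform_amplitude_vox SD of control-point displacements of the
#'   random deformation (0 disables it).
#' @param control_dim Deformation control grid.
#' @param seed Seed.
#' @return A `sigold_stack_set`: list with `truth`, named list `stacks`,
#'   and matching list `transforms`.
#' @export
render_if_stacks <- function(n_stacks, d = c(64, 64, 8), n_blobs = 8,
                             noise_sd = 0.02, max_shift_vox = 2,
                             max_angle_deg = 5, max_log_scale = 0.04,
                             deform_amplitude_vox = 0.8,
                             control_dim = c(4, 4, 2), seed = 1) {
  stopifnot(n_stacks >= 1)
  with_seed(seed, {
    P <- grid_coords(d)
    truth <- numeric(nrow(P))
    for (b in seq_len(n_blobs)) {
      mu <- c(stats::runif(1, 0.25, 0.75) * d[1],
              stats::runif(1, 0.25, 0.75) * d[2],
              stats::runif(1, 0.3, 0.7) * d[3])
      sg <- c(stats::runif(1, 0.05, 0.15) * d[1],
              stats::runif(1, 0.05, 0.15) * d[2],
              stats::runif(1, 0.15, 0.35) * d[3])
      amp <- stats::runif(1, 0.5, 1)
      truth <- truth + amp * exp(-((P[, 1] - mu[1])^2 / (2 * sg[1]^2) +
                                     (P[, 2] - mu[2])^2 / (2 * sg[2]^2) +
                                     (P[, 3] - mu[3])^2 / (2 * sg[3]^2)))
    }
    truth <- array(truth, dim = d)
    stacks <- list()
    transforms <- list()
    for (k in seq_len(n_stacks)) {
      th <- stats::runif(1, -max_angle_deg, max_angle_deg) * pi / 180
      sc <- exp(stats::runif(1, -max_log_scale, max_log_scale))
      A <- diag(3)
      A[1:2, 1:2] <- sc * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      t <- c(stats::runif(2, -max_shift_vox, max_shift_vox),
             stats::runif(1, -max_shift_vox / 4, max_shift_vox / 4))
      disp <- if (deform_amplitude_vox > 0) {
        matrix(stats::rnorm(prod(control_dim) * 3, 0,
                            deform_amplitude_vox),
               prod(control_dim), 3)
      } else NULL
      tf <- make_transform(A = A, t = t, disp = disp,
                           control_dim = control_dim)
      img <- warp_stack(truth, tf)
      img <- img + stats::rnorm(length(img), 0, noise_sd)
      stacks[[sprintf("stack%02d", k)]] <- img
      transforms[[sprintf("stack%02d", k)]] <- tf
    }
    structure(list(truth = truth, stacks = stacks,
                   transforms = transforms, dim = d),
              class = "sigold_stack_set")
  })
}

#' Read or write a stack as multi-page TIFF
#'
#' Each z-slice becomes one page; intensities are stored as 32-bit
#' samples and must lie in \[0, 1\] (rescale before writing).
#'
#' @param arr 3D array with values in \[0, 1\].
#' @param path File path.
#' @return `read_stack_tiff()` returns a 3D array.
#' @export
write_stack_tiff <- function(arr, path) {
  pages <- lapply(seq_len(dim(arr)[3]), function(z) arr[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}
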