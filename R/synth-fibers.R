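#' Parameters for synthetic collagen fiber synthesis
#'
#' Fibers are modelled as smoothed correlated random walks on the pixel grid:
#' each fiber starts at a uniform location with an axial orientation drawn
#' from a (wrapped, axial) von Mises distribution around the fiber set's mean
#' direction, takes unit-pixel steps with small Gaussian heading noise, and
#' spawns side branches as a Poisson process along its arc length. This model
#' gives independent control over exactly the quantities the analysis
#' pipeline measures: length, thickness, junction count and orientation.
#'
#' @param n_fibers number of fiber trees to place (>= 0)
#' @param length_um mean and sd of fiber arc length, micrometers
#' @param thickness_um mean and sd of full fiber thickness, micrometers
#' @param branch_rate expected branch events per 100 um of arc length
#' @param orientation_kappa concentration of the axial orientation
#'   distribution; 0 = isotropic
#' @param mean_direction_deg mean axial direction in degrees, or `NULL` to
#'   draw one uniformly per fiber set
#' @param canvas image size as (height, width) in pixels
#' @param mpp micrometers per pixel (> 0)
#' @param start_rows optional (min, max) row range for fiber seed points,
#'   used to confine e.g. an endocardial band
#' @param wiggle_sd per-step heading noise, radians (curvature of the walk)
#' @param seed integer RNG seed; generation is deterministic given the seed
#' @return an object of class `fiber_params`
#' @export
fiber_params <- function(n_fibers = 50,
                         length_um = c(30, 10),
                         thickness_um = c(1.5, 0.4),
                         branch_rate = 1.5,
                         orientation_kappa = 0.7,
                         mean_direction_deg = NULL,
                         canvas = c(512, 512),
                         mpp = 0.25,
                         start_rows = NULL,
                         wiggle_sd = 0.06,
                         seed = 1L) {
  if (n_fibers < 0) abort("n_fibers must be >= 0")
  if (mpp <= 0) abort("mpp must be > 0")
  if (branch_rate < 0) abort("branch_rate must be >= 0")
  if (orientation_kappa < 0) abort("orientation_kappa must be >= 0")
  if (length(canvas) != 2 || any(canvas < 1)) abort("canvas must be (height, width) >= 1")
  if (thickness_um[1] < mpp) abort("mean thickness must be at least one pixel (%g um)", mpp)
  structure(list(n_fibers = as.integer(n_fibers),
                 length_um = length_um, thickness_um = thickness_um,
                 branch_rate = branch_rate,
                 orientation_kappa = orientation_kappa,
                 mean_direction_deg = mean_direction_deg,
                 canvas = as.integer(canvas), mpp = mpp,
                 start_rows = start_rows, wiggle_sd = wiggle_sd,
                 seed = as.integer(seed)),
            class = "fiber_params")
}

# one correlated random walk; returns pixel points and per-step branch
# spawns. Screen coordinates: +x right (cols), +y down (rows); heading
# measured counter-clockwise, hence rows decrease with sin. The walk stops
# at the canvas boundary; each placed step spawns a branch with probability
# p_branch (Bernoulli thinning of the Poisson branching process).
.walk <- function(r0, c0, dir0, n_steps, wiggle_sd, p_branch, canvas) {
  turns <- if (wiggle_sd > 0) rnorm(n_steps, 0, wiggle_sd) else numeric(n_steps)
  dirs <- dir0 + cumsum(turns)
  rows <- r0 - cumsum(sin(dirs))
  cols <- c0 + cumsum(cos(dirs))
  out <- which(rows < 1 | rows > canvas[1] | cols < 1 | cols > canvas[2])
  k <- if (length(out)) out[1] - 1L else n_steps
  rows <- c(r0, rows[seq_len(k)]); cols <- c(c0, cols[seq_len(k)])
  spawn_at <- if (p_branch > 0 && k > 0) which(runif(k) < p_branch) else integer(0)
  spawns <- lapply(spawn_at, function(i) {
    list(r = rows[i + 1], c = cols[i + 1], dir = dirs[i])
  })
  list(rows = rows, cols = cols, spawns = spawns, steps = k)
}

#' Generate a synthetic fiber set with ground truth
#'
#' Places `n_fibers` random-walk fiber trees on the canvas, records the exact
#' per-fiber arc length, thickness, and branch-event (junction) count, and
#' renders each tree's footprint as a union of discs into a binary truth
#' mask.
#'
#' @param params a [fiber_params()] object
#' @return an object of class `fiber_set`: a list with `fibers` (each with
#'   `points`, `half_width_px`, `thickness_um`, `length_um`, `n_junctions`,
#'   `footprint_px`), the logical `truth_mask`, the `mean_direction_deg`
#'   used, and the generating `params`
#' @export
make_fiber_set <- function(params) {
  stopifnot(inherits(params, "fiber_params"))
  h <- params$canvas[1]; w <- params$canvas[2]
  mean_len_px <- params$length_um[1] / params$mpp
  if (params$n_fibers > 0 &&
      (min(h, w) < 8 || sqrt(h^2 + w^2) < mean_len_px / 4)) {
    abort("canvas %dx%d px is too small to place strokes of mean length %.0f px",
          h, w, mean_len_px)
  }
  withr::with_seed(params$seed, {
    mean_dir <- if (is.null(params$mean_direction_deg)) {
      runif(1, 0, pi)
    } else {
      params$mean_direction_deg * pi / 180
    }
    rr <- params$start_rows %||% c(1, h)
    p_branch <- params$branch_rate / 100 * params$mpp  # per 1-px step
    fibers <- vector("list", params$n_fibers)
    truth <- matrix(FALSE, h, w)
    for (i in seq_len(params$n_fibers)) {
      len_um <- max(2 * params$mpp, rnorm(1, params$length_um[1], params$length_um[2]))
      th_um <- max(params$mpp, rnorm(1, params$thickness_um[1], params$thickness_um[2]))
      half_w <- max(0.5, th_um / (2 * params$mpp))
      n_steps <- max(2L, as.integer(round(len_um / params$mpp)))
      phi <- rvonmises(1, 0, params$orientation_kappa)
      axis_ang <- (mean_dir + phi / 2) %% pi
      dir0 <- axis_ang + sample(c(0, pi), 1)
      r0 <- runif(1, rr[1], rr[2]); c0 <- runif(1, 1, w)
      # walk queue: the main stem plus any spawned branches
      queue <- list(list(r = r0, c = c0, dir = dir0, steps = n_steps))
      all_rows <- numeric(0); all_cols <- numeric(0)
      limbs <- list()
      branch_pts <- matrix(numeric(0), ncol = 2,
                           dimnames = list(NULL, c("row", "col")))
      n_junc <- 0L; total_steps <- 0L
      while (length(queue) > 0) {
        jb <- queue[[1]]; queue <- queue[-1]
        wk <- .walk(jb$r, jb$c, jb$dir, jb$steps, params$wiggle_sd, p_branch,
                    params$canvas)
        all_rows <- c(all_rows, wk$rows); all_cols <- c(all_cols, wk$cols)
        limbs[[length(limbs) + 1]] <- cbind(row = wk$rows, col = wk$cols)
        total_steps <- total_steps + wk$steps
        for (sp in wk$spawns) {
          n_junc <- n_junc + 1L
          branch_pts <- rbind(branch_pts, c(sp$r, sp$c))
          bdir <- sp$dir + sample(c(-1, 1), 1) * runif(1, 0.5, 1.1)
          # branches shorten with generation (subcritical branching), but
          # stay long enough to emerge from the parent stroke footprint
          bsteps <- max(12L, as.integer(round(runif(1, 0.25, 0.6) * jb$steps)))
          queue[[length(queue) + 1]] <- list(r = sp$r, c = sp$c, dir = bdir,
                                             steps = bsteps)
        }
      }
      idx <- stamp_path_c(as.integer(round(all_rows)), as.integer(round(all_cols)),
                          half_w, h, w)
      truth[idx] <- TRUE
      fibers[[i]] <- list(points = cbind(row = all_rows, col = all_cols),
                          limbs = limbs,
                          branch_points = branch_pts,
                          half_width_px = half_w,
                          thickness_um = th_um,
                          length_um = total_steps * params$mpp,
                          n_junctions = n_junc,
                          footprint_px = idx)
    }
    structure(list(fibers = fibers, truth_mask = truth,
                   mean_direction_deg = mean_dir * 180 / pi,
                   params = params),
              class = "fiber_set")
  })
}

# union of two fiber sets on the same canvas
combine_fiber_sets <- function(a, b) {
  stopifnot(identical(dim(a$truth_mask), dim(b$truth_mask)))
  structure(list(fibers = c(a$fibers, b$fibers),
                 truth_mask = a$truth_mask | b$truth_mask,
                 mean_direction_deg = a$mean_direction_deg,
                 params = a$params),
            class = "fiber_set")
}

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("fiber_set: %d fibers on %dx%d px canvas (%.3g um/px), %d truth pixels\n",
              length(x$fibers), nrow(x$truth_mask), ncol(x$truth_mask),
              x$params$mpp, sum(x$truth_mask)))
  invisible(x)
}
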