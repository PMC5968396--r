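# Voxelized blood-flow maps and heterogeneity statistics: histograms,
# relative-flow PDFs, relative dispersion (RD), fractal dimension (FD) from
# the two-resolution RD scaling relation, FD convergence with ensemble size,
# transmural profiles, modality counts, and external (imaging) map ingestion.

#' Construct a voxel blood-flow grid
#'
#' @param values 3D array of per-voxel flow (mm^3/s)
#' @param origin grid corner (mm)
#' @param spacing voxel edge lengths (mm)
#' @param mask logical 3D array of analysis voxels (tissue)
#' @param mass per-voxel mass array (defaults to 1 inside the mask)
#' @return object of class `coro_bfmap`
#' @export
voxel_grid <- function(values, origin, spacing, mask = NULL, mass = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("values: need a 3D array")
  if (any(spacing <= 0)) stop("spacing: must be > 0")
  if (any(values < 0, na.rm = TRUE)) stop("values: flows must be >= 0")
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  if (!identical(dim(mask), dim(values))) stop("mask: shape mismatch")
  if (is.null(mass)) mass <- array(as.numeric(mask), dim(values))
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), mask = mask, mass = mass),
            class = "coro_bfmap")
}

#' Tissue voxel grid skeleton for an anatomy
#'
#' Builds the bounding grid at the requested spacing and marks voxels whose
#' centre lies in tissue.
#'
#' @param anat a `coro_anatomy`
#' @param spacing voxel edge (mm), scalar or length-3
#' @return a `coro_bfmap` with zero values and the tissue mask
#' @export
tissue_grid <- function(anat, spacing = 1) {
  spacing <- rep(spacing, length.out = 3)
  lims <- sapply(1:3, function(i) {
    rng <- range(unlist(lapply(anat$walls, function(w) {
      if (w$type == "ellipsoid") c(w$center[i] - w$semi[i], w$center[i] + w$semi[i])
      else w$point[i]
    })))
    c(floor(rng[1] - 1), ceiling(rng[2] + 1))
  })
  origin <- lims[1, ]
  dims <- pmax(1L, as.integer(ceiling((lims[2, ] - lims[1, ]) / spacing)))
  ctr <- as.matrix(expand.grid(
    x = origin[1] + (seq_len(dims[1]) - 0.5) * spacing[1],
    y = origin[2] + (seq_len(dims[2]) - 0.5) * spacing[2],
    z = origin[3] + (seq_len(dims[3]) - 0.5) * spacing[3]))
  mask <- array(inside_tissue(ctr, anat), dims)
  voxel_grid(array(0, dims), origin, spacing, mask)
}

# voxel linear indices for points; error when out of bounds
voxel_index <- function(p, grid) {
  p <- as_points(p)
  d <- dim(grid$values)
  ix <- sapply(1:3, function(i) floor((p[, i] - grid$origin[i]) / grid$spacing[i]))
  ix <- matrix(ix, ncol = 3)
  if (any(ix < 0) || any(sweep(ix, 2, d, ">=") )) {
    stop("terminal outside grid bounds")
  }
  1L + ix[, 1] + d[1] * (ix[, 2] + d[2] * ix[, 3])
}

#' Terminal-outflow deposits of one placed instance
#'
#' Sums the flow carried by every order-6 terminal into the voxel containing
#' its distal node (half-open voxel bins).
#'
#' @param instance list of placed, solved `coro_tree`s (e.g. `rca`, `lad`)
#' @param grid a `coro_bfmap` skeleton from [tissue_grid()]
#' @return list with `idx` (voxel linear index) and `flow` (mm^3/s)
#' @export
bf_deposits <- function(instance, grid) {
  trees <- Filter(function(x) inherits(x, "coro_tree"), instance)
  idx <- integer(0); q <- numeric(0)
  for (tr in trees) {
    if (is.null(tr$pos) || is.null(tr$flow)) stop("instance trees must be placed and solved")
    term <- terminal_ids(tr)
    idx <- c(idx, voxel_index(tr$pos[term, , drop = FALSE], grid))
    q <- c(q, tr$flow$segment_flows[term])
  }
  agg <- rowsum(q, idx)
  list(idx = as.integer(rownames(agg)), flow = as.numeric(agg))
}

#' Ensemble-averaged voxel blood-flow map
#'
#' Per-instance voxel sums of terminal outflows, arithmetically averaged
#' across the ensemble. Voxels that received flow but whose centre falls
#' outside the tissue mask are added to the mask (with unit mass) so that the
#' map conserves total outflow.
#'
#' @param deposits list of per-instance deposits ([bf_deposits()]), or a list
#'   of placed instances (converted automatically)
#' @param grid a `coro_bfmap` skeleton ([tissue_grid()])
#' @return a `coro_bfmap` with the ensemble-mean values
#' @export
voxelize <- function(deposits, grid) {
  if (length(deposits) == 0) stop("empty ensemble")
  v <- numeric(length(grid$values))
  for (dep in deposits) {
    if (!is.list(dep) || is.null(dep$idx)) dep <- bf_deposits(dep, grid)
    v[dep$idx] <- v[dep$idx] + dep$flow
  }
  v <- v / length(deposits)
  vals <- array(v, dim(grid$values))
  mask <- grid$mask | vals > 0
  mass <- array(as.numeric(mask), dim(vals))
  voxel_grid(vals, grid$origin, grid$spacing, mask, mass)
}

#' Blood-flow histogram of a voxel map
#'
#' Equal-width bins over the masked value range (100 bins for model maps by
#' convention, 600 for imaging maps), with mean and standard deviation of the
#' raw masked voxel values.
#'
#' @param grid a `coro_bfmap`
#' @param n_bins number of bins
#' @return object of class `coro_bfhist`: `breaks`, `counts`, `mids`,
#'   `mean`, `sd`, `n`
#' @export
bf_histogram <- function(grid, n_bins = 100) {
  if (n_bins < 1) stop("n_bins: must be >= 1")
  x <- grid$values[grid$mask]
  if (!length(x)) stop("empty mask")
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(n_bins, findInterval(x, breaks, rightmost.closed = TRUE)),
                     nbins = n_bins)
  structure(list(breaks = breaks, counts = counts,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 mean = mean(x), sd = sd(x), n = length(x)),
            class = "coro_bfhist")
}

#' Relative-flow distribution and relative dispersion
#'
#' Normalizes per-voxel flow to relative flow `d_j = (a_j/m_j) / (A/M)` with
#' voxel masses `m_j` (unity at native resolution; tissue-voxel counts after
#' coarsening). The mass-weighted mean of `d_j` is one by construction, and
#' the binned density integrates to one. The relative dispersion RD is the
#' mass-weighted standard deviation of `d_j` (computed on raw voxel values;
#' binning is for display only).
#'
#' @param grid a `coro_bfmap`
#' @param n_bins bins for the display density
#' @return object of class `coro_rfpdf`: `d`, `mass`, `rd`, `mean`,
#'   `breaks`, `density`
#' @export
relative_flow_pdf <- function(grid, n_bins = 100) {
  a <- grid$values[grid$mask]
  m <- grid$mass[grid$mask]
  A <- sum(a); M <- sum(m)
  if (A <= 0) stop("total perfusion is zero")
  d <- (a / m) / (A / M)
  mbar <- sum(m * d) / M
  rd <- sqrt(sum(m * (d - mbar)^2) / M)
  rng <- range(d)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(n_bins, findInterval(d, breaks, rightmost.closed = TRUE))
  agg <- rowsum(m, bin)
  wcount <- numeric(n_bins)
  wcount[as.integer(rownames(agg))] <- agg
  dens <- wcount / (M * diff(breaks))
  structure(list(d = d, mass = m, rd = rd, mean = mbar,
                 breaks = breaks, density = dens),
            class = "coro_rfpdf")
}

#' Relative dispersion of a voxel map
#' @param grid a `coro_bfmap`
#' @return RD (mass-weighted SD of relative flow)
#' @export
relative_dispersion <- function(grid) relative_flow_pdf(grid)$rd

# block-sum a 3D array by integer factors (extents truncated to multiples)
block_sum <- function(a, f, nd) {
  a <- a[seq_len(nd[1] * f[1]), seq_len(nd[2] * f[2]), seq_len(nd[3] * f[3]),
         drop = FALSE]
  dim(a) <- c(f[1], nd[1], f[2], nd[2], f[3], nd[3])
  s <- colSums(a)                      # nd1 f2 nd2 f3 nd3
  s <- colSums(aperm(s, c(2, 1, 3, 4, 5)))   # nd1 nd2 f3 nd3
  s <- colSums(aperm(s, c(3, 1, 2, 4)))      # nd1 nd2 nd3
  array(s, nd)
}

#' Coarsen a voxel map by integer aggregation factors
#'
#' Flow is extensive: non-overlapping blocks are summed. A coarse voxel is in
#' the mask if any constituent voxel is, and its mass is the number of
#' constituent tissue voxels. Trailing partial blocks at non-divisible
#' extents are truncated (the discarded voxel count is reported via
#' `message()`).
#'
#' @param grid a `coro_bfmap`
#' @param factors integer aggregation factors per axis (default `c(1, 1, 2)`:
#'   paired voxels, mass ratio 2)
#' @return coarsened `coro_bfmap`
#' @export
coarsen <- function(grid, factors = c(1, 1, 2)) {
  f <- as.integer(rep(factors, length.out = 3))
  if (any(f < 1)) stop("factors: must be >= 1 integers")
  d <- dim(grid$values)
  nd <- d %/% f
  lost <- prod(d) - prod(nd * f)
  if (lost > 0) message("coarsen: truncated ", lost, " trailing voxels")
  vals <- block_sum(grid$values, f, nd)
  mass <- block_sum(grid$mass, f, nd)
  maskn <- block_sum(array(as.numeric(grid$mask), d), f, nd) > 0
  mass[mass == 0 & maskn] <- 1
  voxel_grid(vals, grid$origin, grid$spacing * f, maskn, mass)
}

#' Fractal dimension from relative dispersion at two resolutions
#'
#' Inverts the scaling relation `RD(low) = RD(high) * ratio^(1 - D)` where
#' `ratio` is the coarse-to-fine voxel mass ratio:
#' `D = 1 - log(RD_low / RD_high) / log(ratio)`.
#'
#' @param rd_high RD at the reference (high) resolution
#' @param rd_low RD at the coarse resolution
#' @param mass_ratio coarse/fine voxel mass ratio (> 1)
#' @return fractal dimension D (D = 1 iff RD is scale-free)
#' @export
fractal_dimension <- function(rd_high, rd_low, mass_ratio) {
  if (rd_high <= 0 || rd_low <= 0) stop("rd_high/rd_low: must be > 0")
  if (mass_ratio <= 1) stop("mass_ratio: must be > 1")
  1 - log(rd_low / rd_high) / log(mass_ratio)
}

#' Two-resolution heterogeneity summary of a map
#'
#' @param grid a `coro_bfmap` at native (high) resolution
#' @param factors coarsening factors (default paired voxels, mass ratio 2)
#' @return list: `rd_high`, `rd_low`, `mass_ratio`, `fd`
#' @export
heterogeneity <- function(grid, factors = c(1, 1, 2)) {
  rd_h <- relative_dispersion(grid)
  rd_l <- relative_dispersion(coarsen(grid, factors))
  ratio <- prod(factors)
  list(rd_high = rd_h, rd_low = rd_l, mass_ratio = ratio,
       fd = fractal_dimension(rd_h, rd_l, ratio))
}

#' Fit an exponential-decay convergence curve
#'
#' Least-squares fit of `y(n) = A + B * exp(-n / tau)` by profiling `tau`
#' (linear in `A`, `B` at fixed `tau`), returning the asymptote `A`.
#'
#' @param sizes ensemble sizes (>= 4 values)
#' @param values observed quantity per size (e.g. FD)
#' @return list: `A` (asymptote), `B`, `tau`, `fitted`, `residuals`, `sse`
#' @export
fd_convergence_fit <- function(sizes, values) {
  if (length(sizes) < 4) stop("sizes: need at least 4 batch sizes")
  sse_at <- function(tau) {
    X <- cbind(1, exp(-sizes / tau))
    fit <- stats::lm.fit(X, values)
    sum(fit$residuals^2)
  }
  taus <- exp(seq(log(min(sizes) / 5), log(max(sizes) * 5), length.out = 80))
  sse <- vapply(taus, sse_at, numeric(1))
  t0 <- taus[which.min(sse)]
  opt <- optimize(sse_at, c(t0 / 3, t0 * 3), tol = 1e-10)
  tau <- opt$minimum
  X <- cbind(1, exp(-sizes / tau))
  fit <- stats::lm.fit(X, values)
  list(A = unname(fit$coefficients[1]), B = unname(fit$coefficients[2]),
       tau = tau, fitted = as.numeric(X %*% fit$coefficients),
       residuals = as.numeric(fit$residuals), sse = sum(fit$residuals^2))
}

#' Fractal-dimension convergence over cumulative sub-ensembles
#'
#' Computes FD on cumulative sub-ensembles of increasing size and fits the
#' exponential-decay convergence curve.
#'
#' @param deposits per-instance deposit list (control ensemble)
#' @param grid tissue grid skeleton
#' @param batch_sizes cumulative sizes (>= 4, each <= number of instances)
#' @param factors coarsening factors for the FD
#' @return list: `sizes`, `fd`, and the [fd_convergence_fit()] result
#'   (`A` is the asymptotic FD)
#' @export
fd_convergence <- function(deposits, grid, batch_sizes, factors = c(1, 1, 2)) {
  batch_sizes <- sort(unique(as.integer(batch_sizes)))
  if (max(batch_sizes) > length(deposits)) stop("batch size exceeds ensemble")
  fd <- vapply(batch_sizes, function(k) {
    heterogeneity(voxelize(deposits[seq_len(k)], grid), factors)$fd
  }, numeric(1))
  c(list(sizes = batch_sizes, fd = fd), fd_convergence_fit(batch_sizes, fd))
}

#' Distance-to-endocardium map
#'
#' For every masked voxel centre, the distance to the endocardial surface of
#' its own ventricle (region `LV` -> wall `lv_endo`, `RV` -> `rv_endo`).
#'
#' @param anat a `coro_anatomy` with `LV`/`RV` regions
#' @param grid a `coro_bfmap`
#' @return list: `distance` (3D array, NA outside mask), `region` (3D
#'   character array)
#' @export
endocardial_distance_map <- function(anat, grid) {
  d <- dim(grid$values)
  idx <- which(grid$mask)
  ia <- arrayInd(idx, d)
  ctr <- sweep(sweep(ia - 0.5, 2, grid$spacing, "*"), 2, grid$origin, "+")
  reg <- region_of(ctr, anat)
  dist <- rep(NA_real_, length(idx))
  for (rn in names(anat$regions)) {
    sel <- which(reg == rn)
    if (!length(sel)) next
    wname <- if (rn == "LV") "lv_endo" else if (rn == "RV") "rv_endo" else NA
    if (is.na(wname) || is.null(anat$walls[[wname]])) next
    nr <- wall_nearest(anat$walls[[wname]], ctr[sel, , drop = FALSE])
    dist[sel] <- nr$distance
  }
  darr <- array(NA_real_, d); darr[idx] <- dist
  rarr <- array(NA_character_, d); rarr[idx] <- reg
  list(distance = darr, region = rarr)
}

#' Transmural blood-flow profile
#'
#' Collects the per-voxel flow into 1 mm thick layers by distance from the
#' endocardial surface (layer k: distances in `[k, k+1)` mm; the
#' sub-endocardial layer is k = 1, i.e. 1-2 mm) for each ventricle.
#'
#' @param grid a `coro_bfmap`
#' @param dmap result of [endocardial_distance_map()]
#' @param layer_thickness layer thickness (mm)
#' @return named list per ventricle: data frame with `layer`, `flow`
#'   (mm^3/s); layer totals partition the ventricle total
#' @export
transmural_profile <- function(grid, dmap, layer_thickness = 1) {
  out <- list()
  regs <- unique(dmap$region[!is.na(dmap$region)])
  for (rn in sort(regs)) {
    sel <- which(dmap$region == rn & grid$mask)
    lay <- floor(dmap$distance[sel] / layer_thickness)
    fl <- rowsum(grid$values[sel], lay)
    out[[rn]] <- data.frame(layer = as.integer(rownames(fl)),
                            flow = as.numeric(fl))
  }
  out
}

#' Count modes of a histogram
#'
#' Number of local maxima of the moving-average-smoothed density whose
#' prominence exceeds a fraction of the global maximum. Plateaus count once.
#'
#' @param hist a `coro_bfhist` or `coro_rfpdf` (its density is used), or a
#'   numeric vector of bin heights
#' @param smoothing_window moving-average window (bins, default 5)
#' @param prominence_frac prominence threshold as a fraction of the maximum
#'   smoothed density (default 0.05)
#' @return integer mode count
#' @export
modality_count <- function(hist, smoothing_window = 5, prominence_frac = 0.05) {
  y <- if (inherits(hist, "coro_bfhist")) as.numeric(hist$counts)
  else if (inherits(hist, "coro_rfpdf")) as.numeric(hist$density)
  else as.numeric(hist)
  if (!length(y)) stop("empty histogram")
  k <- max(1L, as.integer(smoothing_window))
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- as.numeric(ys)
  # collapse plateaus
  rl <- rle(ys)
  v <- rl$values
  if (length(v) == 1) return(1L)
  thr <- prominence_frac * max(v)
  count <- 0L
  for (i in seq_along(v)) {
    left <- if (i == 1) -Inf else v[i - 1]
    right <- if (i == length(v)) -Inf else v[i + 1]
    if (v[i] > left && v[i] > right) {
      # prominence: drop to the key saddle toward higher ground on each side;
      # a side with no higher ground does not constrain the peak
      lsad <- Inf; j <- i - 1
      while (j >= 1 && v[j] < v[i]) { lsad <- min(lsad, v[j]); j <- j - 1 }
      if (j < 1) lsad <- Inf
      rsad <- Inf; j <- i + 1
      while (j <= length(v) && v[j] < v[i]) { rsad <- min(rsad, v[j]); j <- j + 1 }
      if (j > length(v)) rsad <- Inf
      saddle <- max(lsad[is.finite(lsad)], rsad[is.finite(rsad)], min(v))
      prom <- v[i] - saddle
      if (prom >= thr) count <- count + 1L
    }
  }
  max(count, 1L)
}

#' Load an external voxel blood-flow map (NIfTI)
#'
#' Reads a 3D scalar volume, takes the voxel spacing from the header, and
#' masks out voxels whose value falls outside the threshold range (used to
#' remove residual chamber-blood signal in imaging maps).
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`)
#' @param threshold_range inclusive value range kept in the mask
#' @return a `coro_bfmap`
#' @export
load_external_bf_map <- function(path, threshold_range = c(0, 600)) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("expected a 3D scalar volume, got dims ",
                                  paste(dim(arr), collapse = "x"))
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) stop("missing voxel spacing in header")
  mask <- is.finite(arr) & arr >= threshold_range[1] & arr <= threshold_range[2]
  arr[arr < 0 | !is.finite(arr)] <- 0
  voxel_grid(arr, c(0, 0, 0), sp, mask)
}

#' Write a voxel map as NIfTI
#' @param grid a `coro_bfmap`
#' @param path output `.nii` / `.nii.gz` path
#' @return `path`, invisibly
#' @export
write_bf_map <- function(grid, path) {
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @export
print.coro_bfmap <- function(x, ...) {
  cat("Voxel BF map: ", paste(dim(x$values), collapse = " x "), " voxels @ ",
      paste(x$spacing, collapse = "x"), " mm, ", sum(x$mask),
      " masked, total flow ", format(sum(x$values), digits = 5),
      " mm^3/s\n", sep = "")
  invisible(x)
}
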