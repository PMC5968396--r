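#' @useDynLib coroflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif sd setNames optimize
#' @importFrom utils read.csv write.csv head tail
NULL

# Strahler orders carried by the model: SN 6 (smallest simulated arterioles)
# to SN 11 (main coronary trunks).
ORDERS <- 6:11

#' Load a coronary morphometry table
#'
#' Reads the per-Strahler-order statistics that drive stochastic tree
#' generation: mean element radius, segment length distribution, segments per
#' element, the element connectivity matrix, total-tree-length bounds, blood
#' viscosity, and the porcine-to-human diameter scaling.
#'
#' @param source `"default"` for the packaged fixture, or the path to a YAML
#'   file with keys `orders`, `connectivity`, `length_bounds_mm`,
#'   `viscosity_pa_s`, `human_scale`.
#' @return A validated object of class `coro_morphometry` with components:
#'   `order_stats` (data frame, one row per order 6-11), `connectivity`
#'   (matrix, rows = parent order 7-11, cols = daughter order 6-10),
#'   `length_bounds` (named list), `viscosity` (Pa.s), `human_scale`
#'   (per-order diameter multipliers), and `scaled` (logical; `FALSE` until
#'   [scale_to_human()] has been applied).
#' @export
load_morphometry <- function(source = "default") {
  path <- if (identical(source, "default")) {
    system.file("extdata", "morphometry_default.yaml", package = "coroflow",
                mustWork = TRUE)
  } else {
    if (!file.exists(source)) stop("morphometry source not found: ", source)
    source
  }
  raw <- yaml::read_yaml(path)
  morphometry_from_list(raw)
}

#' Build a morphometry table from a plain list
#'
#' Accepts the same structure as the YAML interface (see [load_morphometry()])
#' already parsed into R lists, validates it, and returns a `coro_morphometry`.
#'
#' @param raw list with `orders`, `connectivity`, `length_bounds_mm`,
#'   `viscosity_pa_s`, `human_scale`.
#' @return validated `coro_morphometry`
#' @export
morphometry_from_list <- function(raw) {
  ord <- do.call(rbind, lapply(raw$orders, function(o) {
    data.frame(order = as.integer(o$order),
               mean_radius = as.numeric(o$mean_radius_mm),
               mean_segment_length = as.numeric(o$mean_segment_length_mm),
               sd_segment_length = as.numeric(o$sd_segment_length_mm),
               segments_per_element = as.numeric(o$segments_per_element))
  }))
  conn <- matrix(0, nrow = 5, ncol = 5,
                 dimnames = list(parent = as.character(7:11),
                                 daughter = as.character(6:10)))
  for (m in names(raw$connectivity)) {
    row <- raw$connectivity[[m]]
    for (n in names(row)) conn[m, n] <- as.numeric(row[[n]])
  }
  lb <- lapply(raw$length_bounds_mm, as.numeric)
  hs <- as.numeric(raw$human_scale)
  tab <- structure(list(order_stats = ord[order(ord$order), , drop = FALSE],
                        connectivity = conn,
                        length_bounds = lb,
                        viscosity = as.numeric(raw$viscosity_pa_s),
                        human_scale = hs,
                        scaled = isTRUE(raw$scaled)),
                   class = "coro_morphometry")
  validate_morphometry(tab)
  tab
}

#' Validate a morphometry table
#'
#' Checks all structural invariants and fails with a message naming the
#' offending field: orders must cover 6..11 exactly, radii must strictly
#' increase with order, lengths/ratios/viscosity/scales must be positive,
#' connectivity entries non-negative with every parent order above 6 expecting
#' at least one daughter, and length bounds ordered min < max.
#'
#' @param tab a `coro_morphometry`
#' @return `tab`, invisibly
#' @export
validate_morphometry <- function(tab) {
  os <- tab$order_stats
  if (!identical(sort(os$order), ORDERS)) {
    stop("order_stats$order: orders must cover 6..11 exactly, got {",
         paste(os$order, collapse = ", "), "}")
  }
  os <- os[order(os$order), ]
  if (any(diff(os$mean_radius) <= 0)) {
    bad <- os$order[which(diff(os$mean_radius) <= 0) + 1L]
    stop("order_stats$mean_radius: must strictly increase with order; ",
         "violated at order ", bad[1])
  }
  for (f in c("mean_radius", "mean_segment_length", "sd_segment_length",
              "segments_per_element")) {
    if (any(!is.finite(os[[f]])) || any(os[[f]] <= 0)) {
      stop("order_stats$", f, ": all values must be finite and > 0")
    }
  }
  if (any(os$segments_per_element < 1)) {
    stop("order_stats$segments_per_element: must be >= 1")
  }
  cm <- tab$connectivity
  if (any(cm < 0)) stop("connectivity: entries must be >= 0")
  if (any(rowSums(cm) < 1)) {
    bad <- rownames(cm)[rowSums(cm) < 1][1]
    stop("connectivity: expected daughter count for parent order ", bad,
         " is < 1 (trees cannot dead-end above order 6)")
  }
  lb <- tab$length_bounds
  for (f in c("rca", "left")) {
    lo <- lb[[paste0(f, "_min")]]; hi <- lb[[paste0(f, "_max")]]
    if (is.null(lo) || is.null(hi) || !(lo < hi) || lo <= 0) {
      stop("length_bounds$", f, "_min/", f, "_max: need 0 < min < max")
    }
  }
  if (!is.finite(tab$viscosity) || tab$viscosity <= 0) {
    stop("viscosity: must be > 0")
  }
  if (length(tab$human_scale) != 6 || any(tab$human_scale <= 0)) {
    stop("human_scale: need 6 positive per-order diameter multipliers")
  }
  invisible(tab)
}

#' Scale a morphometry table to human calibre
#'
#' Multiplies each order's mean radius by the per-order `human_scale`
#' diameter multiplier. The default fixture's uniform 1.25 multiplier anchors
#' the order-11 radius at 1.6 mm, i.e. a 3.2 mm main coronary diameter.
#'
#' @param tab a `coro_morphometry` (unscaled)
#' @return a `coro_morphometry` with scaled radii and `scaled = TRUE`
#' @export
scale_to_human <- function(tab) {
  validate_morphometry(tab)
  if (isTRUE(tab$scaled)) return(tab)
  os <- tab$order_stats
  os$mean_radius <- os$mean_radius * tab$human_scale
  tab$order_stats <- os
  tab$scaled <- TRUE
  validate_morphometry(tab)
  tab
}

#' Serialize a morphometry table to YAML
#'
#' Round-trips through [load_morphometry()]: writing then loading reproduces
#' the table exactly.
#'
#' @param tab a `coro_morphometry`
#' @param path output YAML path
#' @return `path`, invisibly
#' @export
write_morphometry <- function(tab, path) {
  validate_morphometry(tab)
  os <- tab$order_stats
  raw <- list(
    orders = lapply(seq_len(nrow(os)), function(i) list(
      order = os$order[i],
      mean_radius_mm = os$mean_radius[i],
      mean_segment_length_mm = os$mean_segment_length[i],
      sd_segment_length_mm = os$sd_segment_length[i],
      segments_per_element = os$segments_per_element[i])),
    connectivity = {
      cm <- tab$connectivity
      setNames(lapply(rownames(cm), function(m) {
        nz <- cm[m, ][cm[m, ] != 0]
        as.list(nz)
      }), rownames(cm))
    },
    length_bounds_mm = tab$length_bounds,
    viscosity_pa_s = tab$viscosity,
    human_scale = tab$human_scale,
    scaled = tab$scaled)
  yaml::write_yaml(raw, path, precision = 17L)
  invisible(path)
}

# Per-order stats lookup, order in 6..11.
order_row <- function(tab, ord) {
  i <- match(ord, tab$order_stats$order)
  if (any(is.na(i))) stop("invalid order: ", paste(ord[is.na(i)], collapse = ","))
  tab$order_stats[i, , drop = FALSE]
}

# Side-branch order distribution for a parent order m: connectivity row minus
# the two structural order-(m-1) end daughters.
side_branch_weights <- function(tab, m) {
  stopifnot(m >= 7, m <= 11)
  row <- tab$connectivity[as.character(m), ]
  w <- row
  w[as.character(m - 1)] <- max(0, w[as.character(m - 1)] - 2)
  w <- w[as.integer(names(w)) < m]
  w
}

#' @export
print.coro_morphometry <- function(x, ...) {
  cat("Coronary morphometry table (orders 6-11",
      if (x$scaled) ", human-scaled" else ", unscaled", ")\n", sep = "")
  print(x$order_stats, row.names = FALSE)
  cat("viscosity:", format(x$viscosity), "Pa.s\n")
  cat("trunk length bounds [mm]: RCA [", x$length_bounds$rca_min, ", ",
      x$length_bounds$rca_max, "], LAD/LCX [", x$length_bounds$left_min,
      ", ", x$length_bounds$left_max, "]\n", sep = "")
  invisible(x)
}
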