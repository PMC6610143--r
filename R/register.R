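#' Fit a dual-camera registration transform from fiducial localizations
#'
#' In two-camera imaging the channels are related by a small geometric
#' offset. Sub-pixel positions of fiducial beads visible in both channels
#' are paired by mutual nearest neighbour within `gate_px`, and the
#' least-squares transform mapping moving-channel pixel coordinates onto the
#' reference channel is fitted:
#' * `translation` — shift only (>= 1 pair),
#' * `similarity` — rotation + isotropic scale + shift (>= 2 pairs), solved
#'   in closed form via the SVD of the cross-covariance,
#' * `affine` — full 2 x 2 linear map + shift (>= 3 pairs).
#'
#' @param reference_locs,moving_locs tibbles with `x_px`, `y_px`.
#' @param model `"translation"`, `"similarity"` or `"affine"`.
#' @param gate_px pairing gate radius, px.
#' @return a `registration_transform`: list with `model`, `matrix` (2 x 2),
#'   `offset` (length 2), `rmse_px`, `n_pairs`.
#' @export
fit_registration <- function(reference_locs, moving_locs,
                             model = c("affine", "similarity", "translation"),
                             gate_px = 3) {
  model <- match.arg(model)
  pr <- pair_mutual_nn(reference_locs, moving_locs, gate_px)
  need <- c(translation = 1L, similarity = 2L, affine = 3L)[[model]]
  if (nrow(pr) < need) {
    abort(sprintf("model '%s' needs >= %d paired fiducials, found %d.", model, need, nrow(pr)))
  }
  R <- cbind(pr$ref_x, pr$ref_y)
  M <- cbind(pr$mov_x, pr$mov_y)
  if (model == "translation") {
    A <- diag(2)
    b <- colMeans(R) - colMeans(M)
  } else if (model == "similarity") {
    mr <- colMeans(R); mm <- colMeans(M)
    Rc <- sweep(R, 2, mr); Mc <- sweep(M, 2, mm)
    S <- crossprod(Rc, Mc) / nrow(R)          # cov(ref, mov)
    sv <- svd(S)
    d <- sign(det(sv$u %*% t(sv$v)))
    rot <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
    var_m <- sum(Mc^2) / nrow(M)
    s <- sum(diag(diag(c(1, d)) %*% diag(sv$d))) / var_m
    A <- s * rot
    b <- mr - as.vector(A %*% mm)
  } else {
    fx <- lm.fit(cbind(1, M), R[, 1])
    fy <- lm.fit(cbind(1, M), R[, 2])
    A <- rbind(coef(fx)[2:3], coef(fy)[2:3])
    b <- c(coef(fx)[1], coef(fy)[1])
  }
  pred <- sweep(M %*% t(A), 2, -b)
  rmse <- sqrt(mean(rowSums((pred - R)^2)))
  structure(
    list(model = model, matrix = unname(A), offset = unname(b),
         rmse_px = rmse, n_pairs = nrow(pr)),
    class = "registration_transform"
  )
}

#' @export
print.registration_transform <- function(x, ...) {
  cat(sprintf("<registration_transform> %s | %d pairs | rmse %.4g px\n",
              x$model, x$n_pairs, x$rmse_px))
  invisible(x)
}

pair_mutual_nn <- function(a, b, gate) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(ref_x = numeric(), ref_y = numeric(),
                  mov_x = numeric(), mov_y = numeric()))
  }
  d2 <- outer(a$x_px, b$x_px, "-")^2 + outer(a$y_px, b$y_px, "-")^2
  nb_of_a <- apply(d2, 1, which.min)
  na_of_b <- apply(d2, 2, which.min)
  keep <- which(na_of_b[nb_of_a] == seq_len(nrow(a)) &
                  d2[cbind(seq_len(nrow(a)), nb_of_a)] <= gate^2)
  tibble(ref_x = a$x_px[keep], ref_y = a$y_px[keep],
         mov_x = b$x_px[nb_of_a[keep]], mov_y = b$y_px[nb_of_a[keep]])
}

#' Apply (or invert) a registration transform to a localization table
#'
#' Maps `x_px`, `y_px` of the moving channel into the reference frame and
#' recomputes `x_um`, `y_um` when a pixel size is available. The inverse
#' transform round-trips positions to numerical precision.
#'
#' @param transform a `registration_transform` from [fit_registration()].
#' @param locs tibble with `x_px`, `y_px` (and optionally `x_um`, `y_um`).
#' @param pixel_size_um pixel size used to refresh micrometre coordinates;
#'   when `NULL` it is inferred from existing `x_um`/`x_px` columns if
#'   possible.
#' @param inverse apply the inverse mapping.
#' @return `locs` with transformed coordinates.
#' @export
apply_registration <- function(transform, locs, pixel_size_um = NULL,
                               inverse = FALSE) {
  if (!inherits(transform, "registration_transform")) {
    abort("`transform` must come from fit_registration().")
  }
  if (nrow(locs) == 0) return(locs)
  A <- transform$matrix; b <- transform$offset
  if (inverse) {
    A <- solve(transform$matrix)
    b <- -as.vector(A %*% transform$offset)
  }
  P <- cbind(locs$x_px, locs$y_px) %*% t(A)
  locs$x_px <- P[, 1] + b[1]
  locs$y_px <- P[, 2] + b[2]
  if (is.null(pixel_size_um) && all(c("x_um") %in% names(locs))) {
    # infer scale from any row with a nonzero pixel coordinate
    pixel_size_um <- attr(locs, "pixel_size_um")
  }
  if (!is.null(pixel_size_um)) {
    locs$x_um <- locs$x_px * pixel_size_um
    locs$y_um <- locs$y_px * pixel_size_um
  }
  locs
}

#' Serialize / restore a registration transform as JSON
#'
#' @param transform a `registration_transform`.
#' @param path output JSON path.
#' @return `path` (write) or a `registration_transform` (read).
#' @export
write_registration <- function(transform, path) {
  jsonlite::write_json(
    list(model = transform$model, matrix = transform$matrix,
         offset = transform$offset, rmse_px = transform$rmse_px,
         n_pairs = transform$n_pairs),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_registration
#' @export
read_registration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(model = j$model, matrix = matrix(unlist(j$matrix), 2, 2),
         offset = as.numeric(j$offset), rmse_px = j$rmse_px,
         n_pairs = j$n_pairs),
    class = "registration_transform"
  )
}
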