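#' Build design matrices for the social genetic effects model
#'
#' Assembles the incidence structure of
#' `y = Xb + Z_D a_D + Z_S a_S + W l + V g + e`:
#' fixed effects X (sex, test year-month, birth year-month), the identity
#' direct-effect incidence `Z_D`, the social incidence `Z_S` with a 1 in
#' the column of every pen mate (0 on the self column, so each row sums
#' to pen size minus one), the litter incidence `W` and the pen incidence
#' `V` (one 1 per row each). Records missing pen or litter are excluded
#' with a warning; aliased fixed-effect columns are dropped.
#'
#' @param cohort cohort data.frame with `id`, `sex`, `litter`, `pen`,
#'   `test_ym`, `birth_ym`.
#' @param traits data.frame with `id` and the response column.
#' @param trait name of the response column in `traits`.
#' @return an object of class `design_set`.
#' @export
build_design <- function(cohort, traits, trait = "y") {
  stopifnot(trait %in% names(traits))
  d <- merge(cohort, traits[, c("id", trait)], by = "id", sort = FALSE)
  ok <- !is.na(d[[trait]]) & !is.na(d$pen) & !is.na(d$litter) &
    !is.na(d$sex)
  if (!all(ok)) {
    warnf("excluding %d records with missing trait/pen/litter/sex", sum(!ok))
    d <- d[ok, , drop = FALSE]
  }
  n <- nrow(d)
  if (n == 0L) stopf("no usable records")
  y <- d[[trait]]

  fx <- data.frame(sex = factor(d$sex), test_ym = factor(d$test_ym),
                   birth_ym = factor(d$birth_ym))
  keep_terms <- vapply(fx, function(f) nlevels(droplevels(f)) > 1L,
                       logical(1))
  form <- if (any(keep_terms)) {
    stats::as.formula(paste("~", paste(names(fx)[keep_terms],
                                       collapse = " + ")))
  } else ~1
  X <- stats::model.matrix(form, data = fx)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }

  pen <- factor(d$pen)
  litter <- factor(d$litter)
  Vg <- stats::model.matrix(~ pen - 1)
  W <- stats::model.matrix(~ litter - 1)
  # social incidence: pen mates of i get a 1; the self column stays 0
  same_pen <- tcrossprod(Vg)           # 1 when i, j share a pen
  Z_S <- same_pen - diag(n)
  Z_D <- diag(n)

  structure(list(
    y = y, X = X, Z_D = Z_D, Z_S = Z_S, W = W, V = Vg,
    ids = d$id, pen = as.character(d$pen), litter = as.character(d$litter)
  ), class = "design_set")
}

#' @export
print.design_set <- function(x, ...) {
  cat(sprintf(
    "design_set: %d records, %d fixed-effect columns, %d pens, %d litters\n",
    length(x$y), ncol(x$X), ncol(x$V), ncol(x$W)))
  invisible(x)
}
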