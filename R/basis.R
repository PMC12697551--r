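# Cubic B-spline basis over age with interior knots at age quantiles and a
# second-order difference penalty on the spline block. Shared by the
# location-scale-shape and additive quantile fitters.

make_age_basis <- function(age, n_knots = 10, degree = 3) {
  rng <- range(age)
  if (diff(rng) <= 0) {
    stop_fit_error("Degenerate design: all ages identical.")
  }
  n_knots <- max(0L, as.integer(n_knots))
  knots <- if (n_knots > 0) {
    unique(as.numeric(quantile(age, probs = seq_len(n_knots) / (n_knots + 1))))
  } else {
    numeric(0)
  }
  knots <- knots[knots > rng[1] & knots < rng[2]]
  structure(
    list(knots = knots, boundary = rng, degree = degree),
    class = "refcal_basis"
  )
}

eval_basis <- function(basis, age) {
  # clamp evaluation to the training range: bound functions are extended as
  # constants beyond the observed ages rather than extrapolating the spline
  age <- pmin(pmax(age, basis$boundary[1]), basis$boundary[2])
  splines::bs(age,
    knots = basis$knots, degree = basis$degree,
    intercept = TRUE, Boundary.knots = basis$boundary
  )
}

basis_dim <- function(basis) {
  length(basis$knots) + basis$degree + 1L
}

# second-order difference penalty matrix for a coefficient block of size k
diff_penalty <- function(k) {
  if (k < 3) return(matrix(0, k, k))
  D <- diff(diag(k), differences = 2)
  crossprod(D)
}

# design matrix: spline block then a 0/1 male indicator
lss_design <- function(basis, age, sex) {
  cbind(unclass(eval_basis(basis, age)), sexM = as.numeric(sex == "M"))
}

check_sex_levels <- function(sex, sexes = c("F", "M")) {
  bad <- setdiff(unique(as.character(sex)), sexes)
  if (length(bad) > 0) {
    stop_refcal(
      paste0("Unknown sex level(s): ", paste(bad, collapse = ", "),
             ". Expected one of: ", paste(sexes, collapse = ", "), "."),
      "refcal_schema_error"
    )
  }
  invisible(NULL)
}
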