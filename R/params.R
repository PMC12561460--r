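# Kinetic / stoichiometric parameter set and model variants.

.ye_param_table <- function() {
  # name, default, lower, upper, free
  # Defaults are the two-fraction fed-batch reference estimates; bounds are
  # package defaults (documented in the methods vignette) and overridable.
  tab <- rbind(
    q_S_max      = c(0.62,   0.10,  2.0,  1),
    K_S          = c(0.05,   0.05,  0.05, 0),
    q_YEFA_max   = c(1.63,   0.50,  3.0,  1),
    K_YEFA       = c(0.23,   0.01,  5.0,  1),
    q_YEFB_max   = c(0.10,   0.005, 0.5,  1),
    K_YEFB       = c(1.70,   0.01,  5.0,  1),
    d_YE_AB      = c(0.27,   0.0,   1.0,  1),
    d_YE_BC      = c(1.00,   0.0,   1.0,  1),
    Ki_YEFA_qSox = c(0.24,   0.005, 100,  1),
    Ki_YEFB_qSox = c(49.27,  0.005, 100,  1),
    K_qSox       = c(38.11,  0.10,  100,  1),
    Y_AS         = c(0.67,   0.67,  0.67, 0),
    q_Ac_max     = c(0.55,   0.01,  1.5,  1),
    K_A          = c(0.86,   0.05,  2.0,  1),
    Ki_A_S       = c(0.05,   0.005, 5.0,  1),
    q_m          = c(0.04,   0.04,  0.04, 0),
    Y_XS_em      = c(0.43,   0.20,  0.60, 1),
    Y_X_YEFA     = c(0.56,   0.10,  0.80, 1),
    Y_X_YEFB     = c(0.12,   0.01,  0.60, 1),
    Y_XA         = c(0.42,   0.42,  0.42, 0),
    Y_OS         = c(1.07,   1.07,  1.07, 0),
    Y_OA         = c(1.07,   1.07,  1.07, 0),
    Y_O_YE       = c(1.16,   1.16,  1.16, 0),
    C_X          = c(0.0426, 0.0426, 0.0426, 0),
    C_S          = c(0.0333, 0.0333, 0.0333, 0),
    C_A          = c(0.0333, 0.0333, 0.0333, 0),
    C_YE         = c(0.040,  0.040, 0.040, 0)
  )
  colnames(tab) <- c("value", "lower", "upper", "free")
  tab
}

.ye_param_names <- rownames(.ye_param_table())

#' Construct a kinetic parameter set
#'
#' Bundles all kinetic, yield, inhibition and carbon-content parameters of the
#' yeast-extract growth model together with per-parameter box bounds and a
#' free/fixed flag used by [ye_fit()]. Unspecified entries take the package
#' defaults (the two-fraction fed-batch reference estimates).
#'
#' Units: specific rates `q_*` in g g^-1 h^-1, affinities `K_*` and inhibition
#' constants in g L^-1 (except `Ki_YEFA_qSox`, `Ki_YEFB_qSox`, in g g^-1 h^-1,
#' which act on uptake rates), yields `Y_*` in g g^-1, carbon contents `C_*`
#' in mol_C g^-1, distribution parameters `d_YE_AB`, `d_YE_BC` dimensionless
#' in \[0, 1\].
#'
#' @param values named list or numeric vector of parameter values to override.
#' @param lower,upper named numeric vectors of bound overrides.
#' @param free named logical vector; `FALSE` fixes a parameter (its bounds
#'   collapse onto its value).
#' @param check_order if `TRUE`, additionally require the fraction-A uptake
#'   bounds to lie entirely above the fraction-B bounds, encoding the
#'   fast/slow identifiability convention.
#'
#' @return object of class `ye_params`: list with named numeric `value`,
#'   `lower`, `upper` and logical `free`.
#' @examples
#' p <- ye_params(values = list(q_S_max = 0.55), free = c(d_YE_AB = FALSE))
#' p$value[["q_S_max"]]
#' @export
ye_params <- function(values = list(), lower = NULL, upper = NULL,
                      free = NULL, check_order = FALSE) {
  tab <- .ye_param_table()
  value <- tab[, "value"]
  lo <- tab[, "lower"]
  hi <- tab[, "upper"]
  fr <- tab[, "free"] > 0

  ov <- unlist(values)
  if (length(ov)) {
    .check_param_names(names(ov))
    value[names(ov)] <- ov
    # widen default bounds where an override falls outside them
    lo[names(ov)] <- pmin(lo[names(ov)], ov)
    hi[names(ov)] <- pmax(hi[names(ov)], ov)
  }
  if (!is.null(lower)) {
    .check_param_names(names(lower))
    lo[names(lower)] <- lower
  }
  if (!is.null(upper)) {
    .check_param_names(names(upper))
    hi[names(upper)] <- upper
  }
  if (!is.null(free)) {
    .check_param_names(names(free))
    fr[names(free)] <- as.logical(free)
  }
  lo[!fr] <- value[!fr]
  hi[!fr] <- value[!fr]

  p <- structure(list(value = value, lower = lo, upper = hi, free = fr),
                 class = "ye_params")
  validate_params(p, check_order = check_order)
  p
}

.check_param_names <- function(nm) {
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("parameter overrides must be named", call. = FALSE)
  }
  bad <- setdiff(nm, .ye_param_names)
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' Validate a parameter set
#'
#' Checks non-negativity, the \[0, 1\] range of the yeast-extract distribution
#' parameters, the (0, 100\] range of the oxidative-pathway affinity
#' `K_qSox`, that bounds bracket values, that fixed parameters carry equal
#' bounds, and (optionally) the fast/slow ordering of the fraction uptake
#' bounds.
#'
#' @param p a [ye_params()] object.
#' @param check_order require `q_YEFA_max` bounds above `q_YEFB_max` bounds.
#' @return `p`, invisibly; stops on violation.
#' @export
validate_params <- function(p, check_order = FALSE) {
  stopifnot(inherits(p, "ye_params"))
  v <- p$value
  if (any(!is.finite(v))) stop("non-finite parameter value", call. = FALSE)
  if (any(v < 0)) stop("parameters must be >= 0", call. = FALSE)
  for (d in c("d_YE_AB", "d_YE_BC")) {
    if (v[[d]] < 0 || v[[d]] > 1) {
      stop(d, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (v[["K_qSox"]] <= 0 || v[["K_qSox"]] > 100) {
    stop("K_qSox must lie in (0, 100]", call. = FALSE)
  }
  if (any(p$lower > p$value + 1e-12) || any(p$upper < p$value - 1e-12)) {
    stop("bounds must bracket parameter values", call. = FALSE)
  }
  if (any(p$lower[!p$free] != p$upper[!p$free])) {
    stop("fixed parameters must carry equal bounds", call. = FALSE)
  }
  if (check_order) {
    if (p$lower[["q_YEFA_max"]] < p$upper[["q_YEFB_max"]]) {
      stop("fast/slow ordering violated: q_YEFA_max bounds must lie above ",
           "q_YEFB_max bounds", call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.ye_params <- function(x, ...) {
  cat("Yeast-extract growth model parameter set\n")
  df <- data.frame(value = x$value, lower = x$lower, upper = x$upper,
                   free = x$free)
  print(df, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.ye_params <- function(x, ...) {
  data.frame(parameter = names(x$value), value = unname(x$value),
             lower = unname(x$lower), upper = unname(x$upper),
             free = unname(x$free))
}

# replace values of (a subset of) parameters; bounds widen where a new
# value falls outside them (e.g. finite-difference perturbations)
ye_set_values <- function(p, theta) {
  .check_param_names(names(theta))
  p$value[names(theta)] <- theta
  p$lower[names(theta)] <- pmin(p$lower[names(theta)], theta)
  p$upper[names(theta)] <- pmax(p$upper[names(theta)], theta)
  p$lower[!p$free] <- p$value[!p$free]
  p$upper[!p$free] <- p$value[!p$free]
  p
}

## ---- model variants ---------------------------------------------------

.ye_variants <- c("basic", "one_yef", "two_yef", "three_yef")

#' Normalise a model-variant name
#'
#' The model comes in four nested variants: `"basic"` (no yeast extract),
#' `"one_yef"` (all consumable YE in the fast fraction A), `"two_yef"`
#' (fast fraction A plus slow fraction B) and `"three_yef"` (additionally an
#' unconsumed fraction C).
#'
#' @param variant character, case-insensitive; dashes allowed.
#' @return one of `"basic"`, `"one_yef"`, `"two_yef"`, `"three_yef"`.
#' @export
ye_variant <- function(variant) {
  v <- tolower(gsub("[- ]", "_", as.character(variant)[1]))
  if (!v %in% .ye_variants) {
    stop("unknown model variant '", variant, "'; use one of: ",
         paste(.ye_variants, collapse = ", "), call. = FALSE)
  }
  v
}

# logical flags: is fraction A / B kinetically active?
variant_flags <- function(variant) {
  v <- ye_variant(variant)
  switch(v,
    basic     = c(yefa = FALSE, yefb = FALSE),
    one_yef   = c(yefa = TRUE,  yefb = FALSE),
    two_yef   = c(yefa = TRUE,  yefb = TRUE),
    three_yef = c(yefa = TRUE,  yefb = TRUE)
  )
}

#' Apply a variant's structural constraints to a parameter set
#'
#' The single-fraction variant pins both distribution parameters at 1 (all
#' consumable yeast extract in fraction A, no unconsumed fraction); the
#' two-fraction variant pins `d_YE_BC = 1` (no unconsumed fraction). The
#' pinned parameters are also marked fixed so that fitting never moves them.
#' The basic variant leaves values untouched: its reduction (all YE fractions
#' inert) is enforced structurally in the rate equations.
#'
#' @inheritParams validate_params
#' @param variant model variant, see [ye_variant()].
#' @return the constrained `ye_params` object.
#' @export
apply_variant <- function(p, variant) {
  v <- ye_variant(variant)
  pin <- function(p, nm, val) {
    p$value[[nm]] <- val
    p$lower[[nm]] <- val
    p$upper[[nm]] <- val
    p$free[[nm]] <- FALSE
    p
  }
  if (v == "one_yef") {
    p <- pin(p, "d_YE_AB", 1)
    p <- pin(p, "d_YE_BC", 1)
  } else if (v == "two_yef") {
    p <- pin(p, "d_YE_BC", 1)
  }
  p
}

## ---- reference parameter fixtures -------------------------------------

#' Load a packaged reference parameter set
#'
#' Eight reference parameter columns (one per model variant, each estimated
#' on the batch phase alone or on the full batch + fed-batch horizon) ship
#' with the package as plain-text key-value files under
#' `inst/extdata/params/`.
#'
#' @param variant model variant, see [ye_variant()].
#' @param phase `"batch"` or `"fed_batch"` (the full-process column).
#' @return a [ye_params()] object with the variant constraints applied.
#' @examples
#' p <- ye_reference_params("two_yef", "fed_batch")
#' p$value[["q_S_max"]]  # 0.62
#' @export
ye_reference_params <- function(variant = "two_yef", phase = "fed_batch") {
  v <- ye_variant(variant)
  phase <- match.arg(phase, c("batch", "fed_batch"))
  fn <- sprintf("%s_%s.cfg", v, phase)
  path <- system.file("extdata", "params", fn, package = "yegrowth")
  if (!nzchar(path)) stop("missing packaged parameter file ", fn)
  apply_variant(read_params_config(path), v)
}

#' Read a parameter set from a flat key-value config file
#'
#' The format is one `name = value` pair per line (`#` comments allowed);
#' names are the [ye_params()] parameter names, optionally suffixed with
#' `.lower`, `.upper` or `.free` for bound / flag overrides.
#'
#' @param path file path.
#' @return a [ye_params()] object.
#' @export
read_params_config <- function(path) {
  kv <- .read_kv(path)
  nm <- names(kv)
  base <- !grepl("\\.", nm)
  values <- as.list(vapply(kv[base], as.numeric, 0))
  pick <- function(suffix) {
    sel <- grepl(paste0("\\.", suffix, "$"), nm)
    if (!any(sel)) return(NULL)
    out <- vapply(kv[sel], as.numeric, 0)
    names(out) <- sub(paste0("\\.", suffix, "$"), "", nm[sel])
    out
  }
  fr <- pick("free")
  if (!is.null(fr)) fr <- fr > 0
  ye_params(values = values, lower = pick("lower"), upper = pick("upper"),
            free = fr)
}

#' Write a parameter set to a flat key-value config file
#'
#' @inheritParams validate_params
#' @param path file path.
#' @param bounds also write `.lower`/`.upper`/`.free` lines.
#' @return `path`, invisibly.
#' @export
write_params_config <- function(p, path, bounds = TRUE) {
  stopifnot(inherits(p, "ye_params"))
  lines <- sprintf("%s = %.10g", names(p$value), p$value)
  if (bounds) {
    lines <- c(lines,
               sprintf("%s.lower = %.10g", names(p$lower), p$lower),
               sprintf("%s.upper = %.10g", names(p$upper), p$upper),
               sprintf("%s.free = %d", names(p$free), as.integer(p$free)))
  }
  writeLines(lines, path)
  invisible(path)
}

# parse "key = value" lines into a named character vector
.read_kv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  out <- trimws(vapply(parts, `[`, "", 2))
  names(out) <- trimws(vapply(parts, `[`, "", 1))
  out
}
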