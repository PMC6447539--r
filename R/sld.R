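# Scattering length densities of membrane components.
#
# NSLD(T) = sum_i b_i / V(T), XSLD(T) = Z e r_e / V(T); V(T) is piecewise
# linear between tabulated anchors. Neutron values may be negative (hydrogen),
# X-ray values are non-negative.

# coherent bound neutron scattering lengths, fm (Sears tabulation);
# deuterium is a separate symbol "D"
.b_coh_fm <- c(
  H = -3.7390, D = 6.671, C = 6.6460, N = 9.36, O = 5.803, P = 5.13,
  S = 2.847, Na = 3.63, Cl = 9.577, K = 3.67, Ca = 4.70
)

.atomic_number <- c(
  H = 1, D = 1, C = 6, N = 7, O = 8, P = 15,
  S = 16, Na = 11, Cl = 17, K = 19, Ca = 20
)

#' Parse a chemical formula into element counts
#'
#' Understands simple Hill-style formulas such as `"C36H72NO8P"`. Deuterium is
#' written `"D"` and treated as a distinct scattering species.
#'
#' @param formula character scalar.
#' @return named numeric vector of element counts.
#' @examples
#' parse_formula("D2O")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("[0-9]*$", "", toks)
  n <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", toks)))
  n[is.na(n)] <- 1
  counts <- tapply(n, el, sum)
  out <- as.numeric(counts)
  names(out) <- names(counts)
  out
}

#' Define a molecular species
#'
#' A species is a chemical formula plus molecular-volume anchors. The volume at
#' an arbitrary temperature is obtained by linear interpolation between anchors
#' (linear extrapolation from the nearest segment outside; constant if a single
#' anchor is given, i.e. a temperature-independent volume).
#'
#' @param name label.
#' @param formula chemical formula string, or a named count vector.
#' @param volume_anchors two-column matrix-like of (temperature degC,
#'   volume A^3), or a single volume.
#' @return object of class `molecular_species`.
#' @examples
#' d2o <- molecular_species("D2O", "D2O", cbind(c(10, 40), c(30.07, 30.23)))
#' molecular_volume(d2o, 25)
#' @export
molecular_species <- function(name, formula, volume_anchors) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  stopifnot(all(counts > 0), !is.null(names(counts)))
  unknown <- setdiff(names(counts), names(.b_coh_fm))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (length(volume_anchors) == 1L) {
    volume_anchors <- cbind(25, as.numeric(volume_anchors))
  }
  va <- as.matrix(volume_anchors)
  stopifnot(ncol(va) == 2L, all(is.finite(va)), all(va[, 2] > 0))
  va <- va[order(va[, 1]), , drop = FALSE]
  structure(
    list(
      name = name, element_counts = counts, volume_anchors = va,
      electrons = sum(counts * .atomic_number[names(counts)])
    ),
    class = "molecular_species"
  )
}

#' @export
print.molecular_species <- function(x, ...) {
  cat("<molecular_species>", x$name, "\n")
  cat("  formula:", paste0(names(x$element_counts), x$element_counts, collapse = " "),
      " (", x$electrons, "electrons )\n")
  cat("  volume anchors (T degC, A^3):\n")
  print(x$volume_anchors)
  invisible(x)
}

#' Molecular volume at a temperature
#'
#' @param species a `molecular_species` or a name from [species_library()].
#' @param T temperature, degrees Celsius.
#' @return volume in cubic angstrom.
#' @export
molecular_volume <- function(species, T) {
  species <- as_species(species)
  va <- species$volume_anchors
  if (nrow(va) == 1L) return(rep(va[1, 2], length(T)))
  # linear interpolation with linear (not constant) extrapolation
  v <- approx(va[, 1], va[, 2], xout = T, rule = 2)$y
  lo <- T < va[1, 1]
  hi <- T > va[nrow(va), 1]
  if (any(lo)) {
    s <- (va[2, 2] - va[1, 2]) / (va[2, 1] - va[1, 1])
    v[lo] <- va[1, 2] + s * (T[lo] - va[1, 1])
  }
  if (any(hi)) {
    n <- nrow(va)
    s <- (va[n, 2] - va[n - 1, 2]) / (va[n, 1] - va[n - 1, 1])
    v[hi] <- va[n, 2] + s * (T[hi] - va[n, 1])
  }
  if (any(v <= 0)) stop("molecular volume must stay positive")
  v
}

.species_env <- new.env(parent = emptyenv())

#' The shipped species library
#'
#' DMPC, cholesterol, aescin and the two solvents (light and heavy water),
#' with formula and temperature-dependent molecular volumes read from the
#' plain-text JSON table shipped in `extdata/species.json`.
#'
#' @return named list of [molecular_species()] objects.
#' @export
species_library <- function() {
  if (is.null(.species_env$lib)) {
    path <- system.file("extdata", "species.json", package = "memscatter")
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    lib <- lapply(raw$species, function(s) {
      va <- do.call(rbind, lapply(s$volume_anchors, unlist))
      molecular_species(s$name, s$formula, va)
    })
    names(lib) <- vapply(raw$species, `[[`, "", "name")
    .species_env$lib <- lib
  }
  .species_env$lib
}

as_species <- function(x) {
  if (inherits(x, "molecular_species")) return(x)
  if (is.character(x) && length(x) == 1L) {
    lib <- species_library()
    if (!x %in% names(lib)) {
      stop("unknown species '", x, "'; library has: ",
           paste(names(lib), collapse = ", "))
    }
    return(lib[[x]])
  }
  stop("expected a molecular_species or a library species name")
}

#' Scattering length density value
#'
#' Stored on the natural scale (per square angstrom); printed in 1e-6/A^2.
#'
#' @param value SLD in 1/A^2.
#' @param radiation "neutron" or "xray".
#' @param temperature degrees Celsius.
#' @return object of class `sld_value` (a numeric scalar with attributes).
#' @export
sld_value <- function(value, radiation = c("neutron", "xray"), temperature = NA_real_) {
  radiation <- match.arg(radiation)
  stopifnot(is.finite(value))
  if (radiation == "xray" && value < 0) stop("X-ray SLD cannot be negative")
  structure(value, class = "sld_value", radiation = radiation,
            temperature = temperature)
}

#' @export
print.sld_value <- function(x, ...) {
  cat(sprintf("%s SLD: %.4g x 1e-6/A^2 (T = %s degC)\n",
              attr(x, "radiation"), unclass(x) * 1e6,
              format(attr(x, "temperature"))))
  invisible(x)
}

# accept sld_value or bare numeric (1/A^2) in model parameters
as_sld <- function(x) as.numeric(x)

#' Neutron scattering length density
#'
#' NSLD(T) = sum of coherent bound scattering lengths over the molecular
#' volume at temperature T. Hydrogen and deuterium are distinct.
#'
#' @inheritParams molecular_volume
#' @return an [sld_value()].
#' @examples
#' nsld("D2O", 10)   # 6.37e-6 /A^2
#' nsld("DMPC", 10)  # 0.297e-6 /A^2
#' @export
nsld <- function(species, T) {
  species <- as_species(species)
  b <- sum(species$element_counts * .b_coh_fm[names(species$element_counts)]) * 1e-5
  sld_value(b / molecular_volume(species, T), "neutron", T)
}

#' X-ray scattering length density
#'
#' XSLD(T) = (number of electrons) x r_e / V(T) with r_e the classical
#' electron radius, 2.818e-5 angstrom.
#'
#' @inheritParams molecular_volume
#' @return an [sld_value()].
#' @examples
#' xsld("H2O", 10)  # about 9.42e-6 /A^2
#' @export
xsld <- function(species, T) {
  species <- as_species(species)
  sld_value(species$electrons * .r_e / molecular_volume(species, T), "xray", T)
}

#' Mole-fraction mixed scattering length density
#'
#' SLD of an ideal mixture: mole-fraction-weighted total scattering length
#' divided by the mole-fraction-weighted molecular volume (equivalent to
#' volume-fraction averaging of the component SLDs).
#'
#' @param components list of `list(species =, fraction =)` entries; species may
#'   be objects or library names.
#' @param T temperature, degrees Celsius.
#' @param radiation "neutron" or "xray".
#' @return an [sld_value()].
#' @examples
#' mix_sld(list(list(species = "DMPC", fraction = 0.9),
#'              list(species = "cholesterol", fraction = 0.1)), 10, "neutron")
#' @export
mix_sld <- function(components, T, radiation = c("neutron", "xray")) {
  radiation <- match.arg(radiation)
  fr <- vapply(components, function(c) as.numeric(c$fraction), 0)
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("mole fractions must sum to 1 (got ", format(sum(fr)), ")")
  }
  sp <- lapply(components, function(c) as_species(c$species))
  btot <- vapply(sp, function(s) {
    if (radiation == "neutron") {
      sum(s$element_counts * .b_coh_fm[names(s$element_counts)]) * 1e-5
    } else {
      s$electrons * .r_e
    }
  }, 0)
  vtot <- vapply(sp, function(s) molecular_volume(s, T), 0)
  sld_value(sum(fr * btot) / sum(fr * vtot), radiation, T)
}

#' Composition fractions of a DMPC/aescin/cholesterol mixture
#'
#' The two mole fractions use different denominators: the aescin fraction is
#' taken with respect to all three components, while the cholesterol fraction
#' is defined relative to DMPC plus cholesterol only.
#'
#' @param n_DMPC,n_aescin,n_cholesterol mole amounts in any common unit;
#'   `n_DMPC` must be positive, the others non-negative.
#' @return list with `x_aescin` and `x_cholesterol`.
#' @examples
#' composition_fractions(99, 1, 0)   # x_aescin = 0.01
#' composition_fractions(90, 0, 10)  # x_cholesterol = 0.10
#' @export
composition_fractions <- function(n_DMPC, n_aescin = 0, n_cholesterol = 0) {
  stopifnot(n_DMPC > 0, n_aescin >= 0, n_cholesterol >= 0)
  if (n_DMPC + n_cholesterol <= 0) stop("DMPC + cholesterol amount must be positive")
  list(
    x_aescin = n_aescin / (n_aescin + n_DMPC + n_cholesterol),
    x_cholesterol = n_cholesterol / (n_DMPC + n_cholesterol)
  )
}

#' Membrane composition container
#'
#' @inheritParams composition_fractions
#' @return object of class `membrane_composition` with the amounts and derived
#'   fractions.
#' @export
membrane_composition <- function(n_DMPC, n_aescin = 0, n_cholesterol = 0) {
  fr <- composition_fractions(n_DMPC, n_aescin, n_cholesterol)
  structure(
    list(n_DMPC = n_DMPC, n_aescin = n_aescin, n_cholesterol = n_cholesterol,
         x_aescin = fr$x_aescin, x_cholesterol = fr$x_cholesterol),
    class = "membrane_composition"
  )
}

#' @export
print.membrane_composition <- function(x, ...) {
  cat(sprintf("<membrane_composition> x(aescin) = %.4f, x(cholesterol) = %.4f\n",
              x$x_aescin, x$x_cholesterol))
  invisible(x)
}
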