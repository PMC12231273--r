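#' Tensor trace contractions
#'
#' The l-fold traces used in the orientational average of the induced
#' field: the (2:1) trace of a matrix (ordinary trace), the (4:2) double
#' trace of a fourth-order tensor (sum over tensor[i, i, j, j]), and the
#' product trace of two matrices (sum over sigma_ij chi_ji).
#'
#' @param x A 3x3 matrix for `"(2:1)"`, a 3x3x3x3 array for `"(4:2)"`, or
#'   a list of two 3x3 matrices for `"product"`.
#' @param type One of `"(2:1)"`, `"(4:2)"`, `"product"`.
#' @return Scalar.
#' @export
trace_contraction <- function(x, type = c("(2:1)", "(4:2)", "product")) {
  type <- match.arg(type)
  if (type == "(2:1)") {
    if (!is.matrix(x) || !all(dim(x) == c(3, 3))) {
      stop("(2:1) trace needs a 3x3 matrix")
    }
    sum(diag(x))
  } else if (type == "(4:2)") {
    if (!(is.array(x) && length(dim(x)) == 4 && all(dim(x) == 3))) {
      stop("(4:2) trace needs a 3x3x3x3 array")
    }
    tot <- 0
    for (i in 1:3) for (j in 1:3) tot <- tot + x[i, i, j, j]
    tot
  } else {
    if (!is.list(x) || length(x) != 2) {
      stop("product trace needs a list of two 3x3 matrices")
    }
    sum(x[[1]] * t(x[[2]]))
  }
}

#' Second-order field-dependent shift coefficients
#'
#' Assembles, from the zero-field response tensors, the shift
#' delta(B0) = delta0 + (c_indirect + c_direct) * B0^2 where delta0 =
#' -tr(sigma)/3 is the familiar field-independent shift, c_indirect is the
#' residual-shielding-anisotropy (self-orientation) term
#' (beta/mu0) [tr(sigma) tr(chi)/45 - tr(sigma chi)/15], and c_direct =
#' -tau is the intrinsic nonlinear (saturation) response. For isotropic
#' sigma and chi the indirect term cancels exactly.
#'
#' @param resp A [assemble_response()] result (or the sum of an FC and a PC
#'   one via [add_response()]).
#' @param T_K Temperature in kelvin; must match the temperature the
#'   tensors were computed at.
#' @return Object of class `second_order_shift`: `delta0_ppm`,
#'   `c_indirect_ppm_T2`, `c_direct_ppm_T2`, `T_K`, `kind`, `label`.
#' @export
second_order_shift <- function(resp, T_K = resp$T_K) {
  stopifnot(inherits(resp, "response_tensors"))
  if (!isTRUE(all.equal(T_K, resp$T_K))) {
    stop("temperature mismatch: tensors computed at ", resp$T_K,
         " K, shift requested at ", T_K, " K")
  }
  beta <- 1 / (.pnmr_const$kB_au * T_K)
  sig <- resp$sigma
  FBB <- resp$F_BB
  # indirect term written with the raw field second derivative F_BB
  # (chi = -mu0 F_BB, so the 1/mu0 of the beta/mu0 prefactor cancels).
  # (beta/15) tr(sigma chi) - (beta/45) tr(sigma) tr(chi) equals
  # (beta/15) tr(sigma_aniso chi_aniso); the traceless form cancels
  # exactly - not just to roundoff - when either tensor is isotropic
  sig0 <- sig - diag(3) * (trace_contraction(sig) / 3)
  FBB0 <- FBB - diag(3) * (trace_contraction(FBB) / 3)
  c_ind_au <- (beta / 15) * trace_contraction(list(sig0, FBB0), "product")
  c_dir_au <- -resp$tau_au
  to_ppm_T2 <- 1e6 / .pnmr_const$field_au_T^2
  structure(list(delta0_ppm = -trace_contraction(sig) / 3 * 1e6,
                 c_indirect_ppm_T2 = c_ind_au * to_ppm_T2,
                 c_direct_ppm_T2 = c_dir_au * to_ppm_T2,
                 T_K = T_K, kind = resp$kind, label = resp$label),
            class = "second_order_shift")
}

#' @export
print.second_order_shift <- function(x, ...) {
  cat(sprintf("<second_order_shift> %s %s: delta0 = %.6g ppm,", x$label,
              x$kind, x$delta0_ppm))
  cat(sprintf(" c_ind = %.4g, c_dir = %.4g ppm/T^2\n",
              x$c_indirect_ppm_T2, x$c_direct_ppm_T2))
  invisible(x)
}

#' Evaluate a second-order shift at one or more field strengths
#'
#' @param so A [second_order_shift()].
#' @param fields_T Fields in tesla (>= 0); at B0 = 0 the field-independent
#'   shift is returned exactly.
#' @return Numeric vector of shifts in ppm.
#' @export
shift_at_fields <- function(so, fields_T) {
  stopifnot(inherits(so, "second_order_shift"))
  if (any(!is.finite(fields_T)) || any(fields_T < 0)) {
    stop("fields must be finite and non-negative (tesla)")
  }
  so$delta0_ppm +
    (so$c_indirect_ppm_T2 + so$c_direct_ppm_T2) * fields_T^2
}

#' Sum two response-tensor sets (e.g. FC + PC) for the same nucleus
#'
#' The moment-derivative tensors (sigma, tau4) are additive in the
#' coupling operator; the field-only tensors (chi, F_BB) are identical for
#' both kinds and are carried over unchanged.
#'
#' @param a,b `response_tensors` for the same system, nucleus and
#'   temperature.
#' @return A `response_tensors` object of kind `"FC+PC"`.
#' @export
add_response <- function(a, b) {
  stopifnot(inherits(a, "response_tensors"), inherits(b, "response_tensors"))
  if (!isTRUE(all.equal(a$T_K, b$T_K))) stop("temperature mismatch")
  out <- a
  out$sigma <- a$sigma + b$sigma
  out$tau4 <- a$tau4 + b$tau4
  out$tau_au <- a$tau_au + b$tau_au
  out$kind <- paste(a$kind, b$kind, sep = "+")
  out
}
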