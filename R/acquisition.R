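#' Proton gyromagnetic ratio
#'
#' The CODATA value of the proton gyromagnetic ratio, gamma =
#' 2.6752218744e8 rad s^-1 T^-1, used in the Stejskal-Tanner b-value
#' formula.
#'
#' @format numeric scalar, rad s^-1 T^-1.
#' @export
PROTON_GYROMAGNETIC_RATIO <- 2.6752218744e8

#' Construct gradient-pulse configurations
#'
#' @param G numeric, gradient pulse strength in T/m (>= 0).
#' @param delta numeric, gradient pulse duration in s (> 0).
#' @param Delta numeric, time between gradient pulses in s (> 0). Arguments
#'   are recycled to a common length.
#' @return a [GradientConfig-class].
#' @examples
#' cfg <- gradientConfig(G = 0.03, delta = 0.02, Delta = 0.04)
#' bValue(cfg)   # ~859 s/mm^2
#' @export
gradientConfig <- function(G, delta, Delta) {
    n <- max(length(G), length(delta), length(Delta))
    new("GradientConfig", G = rep_len(as.numeric(G), n),
        delta = rep_len(as.numeric(delta), n),
        Delta = rep_len(as.numeric(Delta), n))
}

#' @describeIn bValue Stejskal-Tanner b-value of each configuration:
#'   `gamma^2 G^2 delta^2 (Delta - delta/3)`, converted from s/m^2 to the
#'   conventional s/mm^2 (division by 1e6). Internally all arithmetic is in
#'   SI units (T/m, s); only the returned value is in s/mm^2.
#' @export
setMethod("bValue", "GradientConfig", function(x) {
    validObject(x)
    b_si <- PROTON_GYROMAGNETIC_RATIO^2 * x@G^2 * x@delta^2 *
        (x@Delta - x@delta / 3)   # s/m^2
    b_si / 1e6                    # s/mm^2
})

#' Solve pulse strengths for target b-values
#'
#' Inverts the Stejskal-Tanner relation in closed form: for fixed pulse
#' timings, `G = sqrt(b_SI / (gamma^2 delta^2 (Delta - delta/3)))`, so a
#' phantom or protocol can be specified by its b-values alone.
#'
#' @param targets numeric, target b-values in s/mm^2 (>= 0).
#' @param delta gradient pulse duration in s (> 0).
#' @param Delta time between gradient pulses in s (> `delta/3`).
#' @return a [GradientConfig-class] whose [bValue()] reproduces `targets`
#'   to within 1e-12 relative tolerance.
#' @examples
#' cfg <- configFromBValues(c(0, 100, 1000, 2000), delta = 0.02, Delta = 0.04)
#' bValue(cfg)
#' @export
configFromBValues <- function(targets, delta = 0.02, Delta = 0.04) {
    targets <- as.numeric(targets)
    if (any(!is.finite(targets)) || any(targets < 0))
        stop("'targets' must be finite nonnegative b-values (s/mm^2)")
    denom <- PROTON_GYROMAGNETIC_RATIO^2 * delta^2 * (Delta - delta / 3)
    G <- sqrt(targets * 1e6 / denom)
    gradientConfig(G = G, delta = delta, Delta = Delta)
}
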