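# second, independently written implementation of the spherical-conductor
# dipole field (plain scalar code, no shared helpers) used as an oracle
oracle_dipole_gain <- function(r0_mm, q, sens_mm, ori, center = c(0, 0, 0)) {
  r0 <- (r0_mm - center) * 1e-3
  r <- (sens_mm - center) * 1e-3
  a <- r - r0
  an <- sqrt(sum(a * a))
  rn <- sqrt(sum(r * r))
  FF <- an * (rn * an + rn^2 - sum(r0 * r))
  gF <- (an^2 / rn + sum(a * r) / an + 2 * an + 2 * rn) * r -
    (an + 2 * rn + sum(a * r) / an) * r0
  qx <- c(q[2] * r0[3] - q[3] * r0[2],
          q[3] * r0[1] - q[1] * r0[3],
          q[1] * r0[2] - q[2] * r0[1])
  B <- 1e-7 / FF^2 * (FF * qx - sum(qx * r) * gF)
  sum(B * ori) * 1e6  # fT per nAm
}
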