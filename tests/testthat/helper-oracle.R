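# Deliberately slow scalar-loop reference implementation of the yearly state
# equations (births + survival/migration/education advancement), independent
# of the vectorized engine.

naive_advance <- function(prev, mor, netpim, g, netgim, bm, bf, fer) {
  trans <- education_transitions()
  provs <- dimnames(prev)[[1]]
  nxt <- array(0, dim = dim(prev), dimnames = dimnames(prev))
  for (p in seq_along(provs)) {
    for (si in 1:2) {
      for (a in 0:99) {
        for (edu in 1:7) {
          g_out <- 0
          for (e in 1:6) {
            if (trans$from[e] == edu && trans$gate_age[e] == a) {
              g_out <- g_out + g[p, si, e]
            }
          }
          nxt[p, si, a + 2, edu] <- nxt[p, si, a + 2, edu] +
            prev[p, si, a + 1, edu] * (1 - mor[p, si, a + 1, edu]) *
            (1 + netpim[p, si, a + 1, edu]) * (1 - g_out)
          for (e in 1:6) {
            if (trans$to[e] == edu && trans$gate_age[e] == a) {
              frm <- trans$from[e]
              nxt[p, si, a + 2, edu] <- nxt[p, si, a + 2, edu] +
                prev[p, si, a + 1, frm] * (1 - mor[p, si, a + 1, frm]) *
                (1 + netpim[p, si, a + 1, frm]) * g[p, si, e]
            }
          }
        }
      }
      for (edu in 1:7) { # the open 100+ group retains its own survivors
        nxt[p, si, 101, edu] <- nxt[p, si, 101, edu] +
          prev[p, si, 101, edu] * (1 - mor[p, si, 101, edu]) *
          (1 + netpim[p, si, 101, edu])
      }
      for (a in 1:100) for (edu in 1:7) {
        nxt[p, si, a + 1, edu] <- nxt[p, si, a + 1, edu] * (1 + netgim)
      }
    }
    births <- 0
    for (a in 15:49) for (edu in 1:7) {
      births <- births + prev[p, 2, a + 1, edu] * fer[p, a + 1, edu]
    }
    nxt[p, 1, 1, 1] <- births * bm[[provs[p]]]
    nxt[p, 2, 1, 1] <- births * bf[[provs[p]]]
  }
  nxt
}
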