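# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Brute-force flood fill for 3D connected components: repeated dilation of a
# seed until fixpoint. O(n^2)-ish, fine for grids up to ~20^3.
flood_fill_components <- function(fg, connectivity = 26) {
  dims <- dim(fg)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  labels <- array(0L, dim = dims)
  cur <- 0L
  remaining <- which(fg, arr.ind = TRUE)
  while (nrow(remaining) > 0) {
    cur <- cur + 1L
    frontier <- remaining[1, , drop = FALSE]
    labels[frontier] <- cur
    repeat {
      grew <- FALSE
      for (i in seq_len(nrow(frontier))) {
        for (r in seq_len(nrow(offs))) {
          nb <- frontier[i, ] + offs[r, ]
          if (any(nb < 1) || any(nb > dims)) next
          if (fg[nb[1], nb[2], nb[3]] && labels[nb[1], nb[2], nb[3]] == 0L) {
            labels[nb[1], nb[2], nb[3]] <- cur
            frontier <- rbind(frontier, nb)
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    remaining <- which(fg & labels == 0L, arr.ind = TRUE)
  }
  labels
}

# Exact Cox partial likelihood for tie-free data, evaluated on a beta grid.
# Returns the grid maximizer.
cox_pl_grid_oracle <- function(time, event, x, grid = seq(-5, 5, by = 1e-4)) {
  loglik <- vapply(grid, function(b) {
    ll <- 0
    for (k in which(event == 1)) {
      risk <- time >= time[k]
      ll <- ll + b * x[k] - log(sum(exp(b * x[risk])))
    }
    ll
  }, numeric(1))
  grid[which.max(loglik)]
}

# Grambsch-Therneau score test for a time-varying coefficient, single
# covariate, identity time transform, tie-free data. Built from the
# per-event Schoenfeld residuals and observed information.
zph_score_oracle <- function(coxph_fit) {
  dt <- survival::coxph.detail(coxph_fit)
  s <- residuals(coxph_fit, type = "schoenfeld")
  g <- as.numeric(names(s))
  V <- dt$imat
  c0 <- g - mean(g)
  U <- sum(c0 * s)
  Var <- sum(c0^2 * V) - sum(c0 * V)^2 / sum(V)
  chi <- U^2 / Var
  list(chisq = chi, p = pchisq(chi, 1, lower.tail = FALSE))
}

# Phantom with a single detectable lesion on a quiet background, used by
# several files.
single_lesion_config <- function(radius_mm = 25, suv = 12, seed = 1, ...) {
  phantom_config(
    lesions = data.frame(x = 90, y = 64, z = 64, radius_mm = radius_mm,
      suv = suv),
    seed = seed, ...)
}

# Study condition for Cox parameter recovery: composite-only effect,
# log HR 0.98, administrative follow-up chosen so ~30% of subjects are
# censored.
recovery_config <- function(n, seed) {
  cohort_config(n = n, seed = seed, beta = c(mtv_cga_composite = 0.98),
    admin_horizon = 130, censor_rate = 0)
}
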