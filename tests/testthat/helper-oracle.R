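# Independent monolithic reference implementation of the daily pasture loop.
# Deliberately written as plain per-cell scalar code (no engine, no shared
# flux components) so it can serve as an oracle for the modular dataflow.

oracle_run <- function(landscape, n_days = NULL, harvest_fraction = 0,
                       fertilization = 0) {
  vp <- landscape$vegetation_params
  lp <- landscape$livestock_params
  clim <- landscape$climate
  if (is.null(n_days)) n_days <- nrow(clim)
  com <- landscape$vegetation$values
  com2 <- landscape$overstory$values
  slope <- landscape$slope$values
  nr <- nrow(com); nc <- ncol(com)
  area <- landscape$grid$cell_size^2
  th <- accessibility_thresholds()

  p <- function(code, col) vp[[col]][match(code, vp$code)]
  cal <- function(code, doy) {
    ss <- p(code, "season_start"); se <- p(code, "season_end")
    rd <- p(code, "ramp_days")
    max(0, min(1, min((doy - (ss - rd)) / rd, ((se + rd) - doy) / rd)))
  }
  acc <- function(sp, s) max(0, min(1, (th[[sp]][2] - s) / (th[[sp]][2] - th[[sp]][1])))

  # state arrays
  W <- 0.7 * matrix(p(as.vector(com), "whc"), nr, nc)
  L <- matrix(150, nr, nc); D <- matrix(50, nr, nc); Lit <- matrix(100, nr, nc)
  Nmin <- matrix(5, nr, nc)
  NLit <- matrix(100 * 0.015, nr, nc)
  NL <- 150 * matrix(p(as.vector(com), "n_conc_target"), nr, nc)
  ND <- matrix(50 * 0.01, nr, nc)
  Cr <- matrix(0, nr, nc)
  Wt <- lapply(seq_len(nrow(lp)), function(i) matrix(lp$mean_weight[i], nr, nc))

  out <- list()
  dates <- clim$date
  for (t in seq_len(n_days)) {
    doy <- as.integer(strftime(dates[t], "%j"))
    tm <- clim$tmean_c[t]; pr <- clim$precip_mm[t]; rg <- clim$rg_mj_m2[t]
    snap <- list(
      potential_growth = matrix(NA_real_, nr, nc),
      actual_growth = matrix(NA_real_, nr, nc),
      living = L, dead = D, litter = Lit,
      soil_water = W, soil_mineral_n = Nmin,
      fn = matrix(NA_real_, nr, nc), leaching = matrix(NA_real_, nr, nc),
      intake_total = matrix(NA_real_, nr, nc),
      weights = lapply(Wt, identity)
    )
    W2 <- W; L2 <- L; D2 <- D; Lit2 <- Lit
    Nmin2 <- Nmin; NLit2 <- NLit; NL2 <- NL; ND2 <- ND; Cr2 <- Cr
    Wt2 <- Wt
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      cd <- com[i, j]
      tb <- p(cd, "t_base"); tl <- p(cd, "t_opt_lo")
      thi <- p(cd, "t_opt_hi"); tx <- p(cd, "t_max")
      ft <- if (tm <= tb || tm >= tx) 0
            else if (tm >= tl && tm <= thi) 1
            else if (tm < tl) (tm - tb) / (tl - tb)
            else (tx - tm) / (tx - thi)
      rg2 <- if (cd == com2[i, j]) rg else 0.2 * rg
      fr <- rg2 / (rg2 + p(cd, "rg_half"))
      whc <- p(cd, "whc")
      fh <- min(1, (W[i, j] / whc) / p(cd, "w_crit"))
      pet <- rg / 2.45 * max(0, tm + 5) / 100
      aet <- min(pet * fh, W[i, j] + pr)
      drain <- max(0, W[i, j] + pr - aet - whc)
      ph <- cal(cd, doy)
      pot <- p(cd, "xf") * (ft * fr * fh) * ph
      # nitrogen supply
      dem_n <- pot * p(cd, "n_conc_target")
      cu <- min(dem_n, Cr[i, j])
      ru <- min(max(dem_n - cu, 0), Nmin[i, j])
      rl <- Nmin[i, j] * min(1, drain / whc)
      sc <- if (ru + rl > Nmin[i, j] && ru + rl > 0) Nmin[i, j] / (ru + rl) else 1
      upt <- ru * sc; leach <- rl * sc
      fn <- if (dem_n > 0) min(1, (upt + cu) / dem_n) else 1
      act <- pot * fn
      # grazing demand
      dem <- 0; dshare <- numeric(nrow(lp))
      for (k in seq_len(nrow(lp))) {
        dens <- landscape$livestock_densities[[lp$group_id[k]]]$values[i, j]
        dshare[k] <- dens / area * lp$intake_max[k] * acc(lp$species[k], slope[i, j])
        dem <- dem + dshare[k]
      }
      pal <- p(cd, "palatability")
      sl <- pal * L[i, j]; sd <- pal * D[i, j]
      itot <- min(dem, sl + sd)
      ril <- min(itot, sl); rid <- itot - ril
      # living pool rescale
      sen_raw <- L[i, j] * p(cd, "senescence_rate") * (1 - ph)
      harv_raw <- L[i, j] * harvest_fraction
      outl <- sen_raw + harv_raw + ril
      s1 <- if (outl > L[i, j] + act && outl > 0) (L[i, j] + act) / outl else 1
      sen <- sen_raw * s1; harv <- harv_raw * s1; il <- ril * s1
      # dead pool rescale
      lit_raw <- D[i, j] * p(cd, "litterfall_rate")
      outd <- lit_raw + rid
      s2 <- if (outd > D[i, j] + sen && outd > 0) (D[i, j] + sen) / outd else 1
      lit <- lit_raw * s2; id <- rid * s2
      dec <- Lit[i, j] * p(cd, "k_min") * ft * fh
      # nitrogen fluxes
      cl <- if (L[i, j] > 0) NL[i, j] / L[i, j] else 0
      cdn <- if (D[i, j] > 0) ND[i, j] / D[i, j] else 0
      rsn <- sen * cl; riln <- il * cl
      outn <- rsn + riln
      s3 <- if (outn > NL[i, j] + upt + cu && outn > 0) (NL[i, j] + upt + cu) / outn else 1
      senn <- rsn * s3; iln <- riln * s3
      reab <- senn * p(cd, "reabs_fraction")
      tod <- senn - reab
      rln <- lit * cdn; ridn <- id * cdn
      outdn <- rln + ridn
      s4 <- if (outdn > ND[i, j] + tod && outdn > 0) (ND[i, j] + tod) / outdn else 1
      litn <- rln * s4; idn <- ridn * s4
      minz <- NLit[i, j] * p(cd, "k_min") * ft * fh
      ingn <- iln + idn
      if (dem > 0) {
        ret <- sum(dshare * lp$n_retention) / dem
        sfr <- sum(dshare * lp$solid_fraction) / dem
      } else { ret <- 0; sfr <- 0 }
      solid <- ingn * (1 - ret) * sfr
      urine <- ingn * (1 - ret) * (1 - sfr)
      # livestock weights
      sat <- if (dem > 0) (il + id) / dem else 1
      for (k in seq_len(nrow(lp))) {
        dens <- landscape$livestock_densities[[lp$group_id[k]]]$values[i, j]
        if (dens > 0) {
          per <- sat * lp$intake_max[k] * acc(lp$species[k], slope[i, j])
          dig <- per * p(cd, "digestibility")
          dw <- lp$conversion_eff[k] * (dig - lp$maintenance_coeff[k] * Wt[[k]][i, j])
          Wt2[[k]][i, j] <- max(0, Wt[[k]][i, j] + dw)
        }
      }
      # pool updates
      W2[i, j] <- W[i, j] + pr - aet - drain
      L2[i, j] <- max(0, L[i, j] + act - sen - harv - il)
      D2[i, j] <- max(0, D[i, j] + sen - lit - id)
      Lit2[i, j] <- max(0, Lit[i, j] + lit - dec)
      Nmin2[i, j] <- max(0, Nmin[i, j] + minz + urine + fertilization - upt - leach)
      NLit2[i, j] <- max(0, NLit[i, j] + litn + solid - minz)
      NL2[i, j] <- max(0, NL[i, j] + upt + cu - senn - iln)
      ND2[i, j] <- max(0, ND[i, j] + tod - litn - idn)
      Cr2[i, j] <- max(0, Cr[i, j] + reab - cu)
      snap$potential_growth[i, j] <- pot
      snap$actual_growth[i, j] <- act
      snap$fn[i, j] <- fn
      snap$leaching[i, j] <- leach
      snap$intake_total[i, j] <- il + id
    }
    out[[t]] <- snap
    W <- W2; L <- L2; D <- D2; Lit <- Lit2
    Nmin <- Nmin2; NLit <- NLit2; NL <- NL2; ND <- ND2; Cr <- Cr2
    Wt <- Wt2
  }
  out
}
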