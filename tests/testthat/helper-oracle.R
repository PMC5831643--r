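# Independent reference implementation of the planner, written in plain R on
# top of the exported module functions (beliefs, irritation, game rules).
# It recomputes, without any of the engine's storage tricks, the same
# quantities as the compiled shared-tree engine: per-slot, per-level policies
# and values, belief filtering along every branch, and the round-by-round
# assessment of a subject along an observed exchange.

O_AMTS <- c(0L, 5L, 10L, 15L, 20L)
O_ALPHA <- c(0, 0.4, 1)

o_nret <- function(ii) length(tg_return_grid(O_AMTS[ii]))

o_role_of <- function(ctx, l) {
  if ((ctx$tom - l) %% 2 == 0) ctx$role else
    setdiff(c("investor", "trustee"), ctx$role)
}

o_tables <- function(ctx) {
  polT <- lapply(O_ALPHA, function(a)
    lapply(O_AMTS, function(aI) {
      g <- tg_return_grid(aI)
      softmax_policy(
        vapply(g, function(aT) tg_utility("trustee", aI, aT, a), 0), ctx$beta)
    }))
  polI <- lapply(O_ALPHA, function(a) {
    q <- vapply(seq_along(O_AMTS), function(ii) {
      aI <- O_AMTS[ii]
      g <- tg_return_grid(aI)
      mean(vapply(1:3, function(a2)
        sum(polT[[a2]][[ii]] *
              vapply(g, function(aT)
                tg_utility("investor", aI, aT, a, ctx$omega), 0)), 0))
    }, 0)
    softmax_policy(q, ctx$beta)
  })
  irrT <- lapply(O_AMTS, function(aI)
    irritated_policy("trustee", aI = aI))
  irrI <- irritated_policy("investor", omega = ctx$omega)
  EunifT <- vapply(O_AMTS, function(aI) mean(tg_return_grid(aI)), 0)
  list(polT = polT, polI = polI, irrT = irrT, irrI = irrI,
       EunifT = EunifT, EunifI = mean(O_AMTS))
}

o_init_beliefs <- function(ctx) {
  lapply(0:ctx$tom, function(l) tg_belief(q = ctx$awareness))
}

## investor-parity level: predictions of the trustee per own investment
o_calc_inv <- function(B, polTlm1, Einv_lm1, tab) {
  pa <- B$guilt / sum(B$guilt)
  pz <- B$irritability / sum(B$irritability)
  track <- list(); pred <- list(); pibar <- list(); EretT <- numeric(5)
  for (ii in 1:5) {
    fav <- classify_action(O_AMTS[ii], Einv_lm1)
    Btr <- update_partner_irritation(B, fav)
    track[[ii]] <- Btr$track
    nr <- o_nret(ii)
    pimat <- vapply(1:3, function(a) polTlm1[[a]][[ii]], numeric(nr))
    pimat <- matrix(pimat, nrow = nr)
    pred[[ii]] <- predicted_partner_policy(Btr, pimat, tab$irrT[[ii]][1:nr])
    pibar[[ii]] <- as.numeric(pimat %*% pa)
    EretT[ii] <- sum(tg_return_grid(O_AMTS[ii]) * pred[[ii]])
  }
  list(pa = pa, pz = pz, track = track, pred = pred, pibar = pibar,
       EretT = EretT)
}

o_edge_inv <- function(B, calc, polTlm1, tab, ii, j) {
  nb <- B
  nb$track <- calc$track[[ii]]
  if (ii > 1) {
    tr <- calc$track[[ii]]
    lik_a <- vapply(1:3, function(i)
      sum(calc$pz * ((1 - tr) * polTlm1[[i]][[ii]][j] +
                       tr * tab$irrT[[ii]][j])), 0)
    nb <- update_guilt(nb, lik_a)
    lik_z <- (1 - tr) * calc$pibar[[ii]][j] + tr * tab$irrT[[ii]][j]
    nb <- update_irritability(nb, lik_z)
  }
  nb
}

## trustee-parity level: predictions of the investor
o_calc_tru <- function(B, polIlm1, tab) {
  pa <- B$guilt / sum(B$guilt)
  pz <- B$irritability / sum(B$irritability)
  pimat <- vapply(1:3, function(a) polIlm1[[a]], numeric(5))
  pred <- predicted_partner_policy(B, matrix(pimat, nrow = 5), tab$irrI)
  pibar <- as.numeric(matrix(pimat, nrow = 5) %*% pa)
  list(pa = pa, pz = pz, pred = pred, pibar = pibar,
       EinvI = sum(O_AMTS * pred))
}

o_edge_tru <- function(B, calc, polIlm1, EretT_lm1, tab, ii, j) {
  lik_a <- vapply(1:3, function(i)
    sum(calc$pz * ((1 - B$track) * polIlm1[[i]][ii] + B$track * tab$irrI[ii])),
    0)
  nb <- update_guilt(B, lik_a)
  lik_z <- (1 - B$track) * calc$pibar[ii] + B$track * tab$irrI[ii]
  nb <- update_irritability(nb, lik_z)
  if (ii > 1) {
    ret <- tg_return_grid(O_AMTS[ii])[j]
    nb <- update_partner_irritation(nb,
                                    classify_action(ret, EretT_lm1[ii]))
  }
  nb
}

o_key <- function(ii, j) paste0(O_AMTS[ii], ":", tg_return_grid(O_AMTS[ii])[j])

o_build <- function(depth, H) {
  node <- list(depth = depth, lev = list())
  if (depth < H - 1) {
    node$children <- list()
    for (ii in 1:5)
      for (j in seq_len(o_nret(ii)))
        node$children[[o_key(ii, j)]] <- o_build(depth + 1, H)
  }
  node
}

## one full pass of level l over the (sub)tree rooted at `node`
o_pass <- function(node, l, B, ctx, tab) {
  rl <- o_role_of(ctx, l)
  res <- list(B = B, role = rl)
  if (rl == "investor") {
    polTlm1 <- if (l == 0) tab$polT else node$lev[[l]]$polT
    Einv <- if (l == 0) tab$EunifI else node$lev[[l]]$EinvI
    calc <- o_calc_inv(B, polTlm1, Einv, tab)
    res$calc <- calc
    if (!is.null(node$children))
      for (ii in 1:5)
        for (j in seq_len(o_nret(ii))) {
          nb <- o_edge_inv(B, calc, polTlm1, tab, ii, j)
          key <- o_key(ii, j)
          node$children[[key]] <- o_pass(node$children[[key]], l, nb, ctx, tab)
        }
    Q <- list(); pol <- list(); V <- numeric(3)
    for (a in 1:3) {
      qa <- numeric(5)
      for (ii in 1:5) {
        g <- tg_return_grid(O_AMTS[ii])
        contv <- vapply(seq_along(g), function(j) {
          if (is.null(node$children)) 0
          else node$children[[o_key(ii, j)]]$lev[[l + 1]]$V[a]
        }, 0)
        u <- vapply(seq_along(g), function(j)
          tg_utility("investor", O_AMTS[ii], g[j], O_ALPHA[a], ctx$omega), 0)
        qa[ii] <- sum(calc$pred[[ii]] * (u + contv))
      }
      Q[[a]] <- qa
      pol[[a]] <- softmax_policy(qa, ctx$beta)
      V[a] <- sum(pol[[a]] * qa)
    }
    res$Q <- Q; res$polI <- pol; res$V <- V
    res$EretT <- calc$EretT; res$pred <- calc$pred
  } else {
    polIlm1 <- if (l == 0) tab$polI else node$lev[[l]]$polI
    EretT_lm1 <- if (l == 0) tab$EunifT else node$lev[[l]]$EretT
    calc <- o_calc_tru(B, polIlm1, tab)
    res$calc <- calc
    if (!is.null(node$children))
      for (ii in 1:5)
        for (j in seq_len(o_nret(ii))) {
          nb <- o_edge_tru(B, calc, polIlm1, EretT_lm1, tab, ii, j)
          key <- o_key(ii, j)
          node$children[[key]] <- o_pass(node$children[[key]], l, nb, ctx, tab)
        }
    Q <- list(); pol <- list(); V <- numeric(3)
    for (a in 1:3) {
      Qa <- list(); pola <- list(); Va <- 0
      for (ii in 1:5) {
        g <- tg_return_grid(O_AMTS[ii])
        qv <- vapply(seq_along(g), function(j) {
          cont <- if (is.null(node$children)) 0
          else node$children[[o_key(ii, j)]]$lev[[l + 1]]$V[a]
          tg_utility("trustee", O_AMTS[ii], g[j], O_ALPHA[a]) + cont
        }, 0)
        Qa[[ii]] <- qv
        pola[[ii]] <- softmax_policy(qv, ctx$beta)
        Va <- Va + calc$pred[ii] * sum(pola[[ii]] * qv)
      }
      Q[[a]] <- Qa
      pol[[a]] <- pola
      V[a] <- Va
    }
    res$Q <- Q; res$polT <- pol; res$V <- V
    res$EinvI <- calc$EinvI; res$pred <- calc$pred
  }
  node$lev[[l + 1]] <- res
  node
}

o_run <- function(ctx, beliefs, H, tab) {
  tree <- o_build(0, H)
  for (l in 0:ctx$tom) tree <- o_pass(tree, l, beliefs[[l + 1]], ctx, tab)
  tree
}

## full replay of a subject along an observed exchange; mirrors the engine's
## per-round assessment and advance
o_assess <- function(params, investments, repayments) {
  ctx <- params
  tab <- o_tables(ctx)
  beliefs <- o_init_beliefs(ctx)
  own <- own_irritation(ctx$zeta)
  R <- length(investments)
  rec <- list()
  for (r in seq_len(R)) {
    H <- min(ctx$plan, 10 - r + 1)
    tree <- o_run(ctx, beliefs, H, tab)
    ii <- match(investments[r], O_AMTS)
    g <- tg_return_grid(investments[r])
    j <- match(repayments[r], g)
    root <- tree$lev
    k1 <- ctx$tom + 1
    aidx <- match(ctx$alpha, O_ALPHA)
    if (ctx$role == "investor") {
      planned <- root[[k1]]$polI[[aidx]]
      mix <- mix_policies(planned, tab$irrI, own$v)
      rec[[r]] <- list(planned = planned, mixture = mix, v = own$v,
                       p_obs = mix[ii],
                       expectation = root[[k1]]$EretT[ii],
                       forced = FALSE,
                       pred = root[[k1]]$pred[[ii]])
    } else {
      vdec <- update_own_irritation(
        own, classify_action(investments[r], root[[k1]]$EinvI))$v
      planned <- root[[k1]]$polT[[aidx]][[ii]]
      irr <- tab$irrT[[ii]][seq_along(g)]
      mix <- mix_policies(planned, irr, vdec)
      rec[[r]] <- list(planned = planned, mixture = mix, v = vdec,
                       p_obs = if (ii == 1) 1 else mix[j],
                       expectation = root[[k1]]$EinvI,
                       forced = (ii == 1),
                       pred = root[[k1]]$pred)
    }
    ## advance beliefs and own irritation with the actual outcome
    newb <- beliefs
    for (l in 0:ctx$tom) {
      res <- root[[l + 1]]
      if (res$role == "investor") {
        polTlm1 <- if (l == 0) tab$polT else root[[l]]$polT
        newb[[l + 1]] <- o_edge_inv(beliefs[[l + 1]], res$calc, polTlm1, tab,
                                    ii, j)
      } else {
        polIlm1 <- if (l == 0) tab$polI else root[[l]]$polI
        EretT_lm1 <- if (l == 0) tab$EunifT else root[[l]]$EretT
        newb[[l + 1]] <- o_edge_tru(beliefs[[l + 1]], res$calc, polIlm1,
                                    EretT_lm1, tab, ii, j)
      }
    }
    beliefs <- newb
    if (ctx$role == "investor") {
      if (ii > 1)
        own <- update_own_irritation(
          own, classify_action(repayments[r],
                               root[[ctx$tom + 1]]$EretT[ii]))
    } else {
      own <- update_own_irritation(
        own, classify_action(investments[r], root[[ctx$tom + 1]]$EinvI))
    }
  }
  rec
}

## flatten an oracle tree into path -> per-level results (paths match the
## engine's dump format)
o_flatten <- function(tree, prefix = "") {
  out <- list()
  out[[if (prefix == "") "." else prefix]] <- tree$lev
  if (!is.null(tree$children))
    for (key in names(tree$children)) {
      child_prefix <- if (prefix == "") key else paste0(prefix, "|", key)
      out <- c(out, o_flatten(tree$children[[key]], child_prefix))
    }
  out
}

## compare an engine tree dump against the oracle on every slot and level
o_compare_tree <- function(params, investments = integer(0),
                           repayments = integer(0), tol = 1e-10) {
  ctx <- params
  dump <- trustgame:::cpp_tree_dump(
    trustgame:::params_ctx(params), as.integer(investments),
    as.integer(repayments))
  ## oracle: replay beliefs to the current node, then run the tree
  tab <- o_tables(ctx)
  beliefs <- o_init_beliefs(ctx)
  R <- length(investments)
  if (R > 0) {
    ## derive the beliefs at the current node by replaying edge updates
    for (r in seq_len(R)) {
      H <- min(ctx$plan, 10 - r + 1)
      tree <- o_run(ctx, beliefs, H, tab)
      ii <- match(investments[r], O_AMTS)
      j <- match(repayments[r], tg_return_grid(investments[r]))
      root <- tree$lev
      newb <- beliefs
      for (l in 0:ctx$tom) {
        res <- root[[l + 1]]
        if (res$role == "investor") {
          polTlm1 <- if (l == 0) tab$polT else root[[l]]$polT
          newb[[l + 1]] <- o_edge_inv(beliefs[[l + 1]], res$calc, polTlm1,
                                      tab, ii, j)
        } else {
          polIlm1 <- if (l == 0) tab$polI else root[[l]]$polI
          EretT_lm1 <- if (l == 0) tab$EunifT else root[[l]]$EretT
          newb[[l + 1]] <- o_edge_tru(beliefs[[l + 1]], res$calc, polIlm1,
                                      EretT_lm1, tab, ii, j)
        }
      }
      beliefs <- newb
    }
  }
  H <- min(ctx$plan, 10 - R)
  otree <- o_run(ctx, beliefs, H, tab)
  oflat <- o_flatten(otree)

  worst <- 0
  for (s in seq_along(dump$slots)) {
    slot <- dump$slots[[s]]
    path <- if (slot$path == "") "." else slot$path
    olev <- oflat[[path]]
    if (is.null(olev)) stop("oracle has no slot for path ", path)
    for (l in 0:ctx$tom) {
      el <- slot$levels[[l + 1]]
      ol <- olev[[l + 1]]
      worst <- max(worst, abs(el$d - ol$B$guilt),
                   abs(el$w - ol$B$irritability),
                   abs(el$v - ol$B$track),
                   abs(el$V - ol$V))
      if (ol$role == "investor") {
        for (a in 1:3) {
          worst <- max(worst, abs(el$Q[a, ] - ol$Q[[a]]),
                       abs(el$pol[a, ] - ol$polI[[a]]))
        }
        worst <- max(worst, abs(el$Eret - ol$EretT))
      } else {
        for (a in 1:3)
          for (ii in 1:5) {
            nr <- o_nret(ii)
            worst <- max(worst,
                         abs(el$Q[a, ii, seq_len(nr)] - ol$Q[[a]][[ii]]),
                         abs(el$pol[a, ii, seq_len(nr)] - ol$polT[[a]][[ii]]))
          }
        worst <- max(worst, abs(el$Einv - ol$EinvI))
      }
    }
  }
  worst
}
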