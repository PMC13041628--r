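# Shared fixtures built in code.

# Small two-class categorical data generator for LCA recovery tests.
simulate_lca_data <- function(n, pi_k, rho, seed) {
  set.seed(seed)
  K <- length(pi_k)
  J <- length(rho)
  cls <- sample.int(K, n, replace = TRUE, prob = pi_k)
  x <- matrix(0L, n, J)
  for (j in seq_len(J)) {
    for (k in seq_len(K)) {
      sel <- cls == k
      if (any(sel))
        x[sel, j] <- sample.int(length(rho[[j]][k, ]), sum(sel),
                                replace = TRUE, prob = rho[[j]][k, ])
    }
  }
  list(data = x, class = cls)
}

# Well-separated item-response profiles: peak probability `pk` on a
# class-specific category of a 3-category item.
separated_rho <- function(K, J, pk = 0.85) {
  lapply(seq_len(J), function(j) {
    r <- matrix((1 - pk) / 2, K, 3)
    for (k in seq_len(K)) r[k, ((k + j) %% 3) + 1] <- pk
    r
  })
}

# Greedy total-variation alignment of estimated classes to true classes.
align_by_tv <- function(rho_est, rho_true) {
  K <- nrow(rho_est[[1]])
  tv <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in seq_len(K))
    tv[a, b] <- sum(vapply(seq_along(rho_est),
                           function(j) sum(abs(rho_est[[j]][a, ] - rho_true[[j]][b, ])),
                           numeric(1)))
  map <- integer(K)
  used_r <- used_c <- rep(FALSE, K)
  for (s in seq_len(K)) {
    m <- tv
    m[used_r, ] <- Inf; m[, used_c] <- Inf
    idx <- which(m == min(m), arr.ind = TRUE)[1, ]
    map[idx[1]] <- idx[2]
    used_r[idx[1]] <- TRUE; used_c[idx[2]] <- TRUE
  }
  map  # map[est] = true
}

# A tiny hand-built population (complete graph) for engine-level tests.
tiny_population <- function(b_step, a_tv = 0, a_dg = 0, a_pr = 0,
                            edges = NULL) {
  n <- length(b_step)
  agents <- data.frame(id = seq_len(n), class_modal = 1L,
                       a_tv = a_tv, a_dg = a_dg, a_pr = a_pr,
                       b_step = b_step, baseline_propensity = b_step,
                       observed_uptake = 0L,
                       degree_target = 2L, task = "vaccination")
  post <- matrix(0, n, 6); post[, 1] <- 1
  attr(agents, "posterior") <- post
  if (is.null(edges)) {
    edges <- t(combn(n, 2))  # complete graph
  }
  net <- layered_network(n, edges, matrix(integer(0), 0, 2))
  list(agents = agents, net = net, task = "vaccination")
}

# Exact distribution of the 12-step dynamics on tiny graphs by full
# enumeration: averages over both phase permutations and all per-agent
# Bernoulli outcomes, using the same transition formulas but implemented
# independently of the C++ engine.
exact_final_adoption_mean <- function(pop, spec, params) {
  agents <- pop$agents
  n <- nrow(agents)
  expo <- campaignsim::agent_exposure(spec, agents, params)
  nbrs <- lapply(seq_len(n), function(i) union_neighbors(pop$net, i))
  deg <- lengths(nbrs)
  perms <- if (n == 2) list(1:2, 2:1) else {
    do.call(c, lapply(1:3, function(a) lapply(setdiff(1:3, a), function(b)
      c(a, b, setdiff(1:3, c(a, b))))))
  }

  enum_phase <- function(state, phase) {
    # returns list of (prob, state) after one sequential phase in a given
    # agent order, enumerated over permutations and outcomes
    out <- list()
    for (perm in perms) {
      walk <- function(st, idx, pr) {
        if (idx > n) { out[[length(out) + 1]] <<- list(pr / length(perms), st); return() }
        i <- perm[idx]
        eligible <- if (phase == 1) st[i] == 0 else st[i] == 1
        if (!eligible) { walk(st, idx + 1, pr); return() }
        if (phase == 1) {
          frac <- if (deg[i] > 0) mean(st[nbrs[[i]]] >= 1) else 0
          p <- campaignsim::awareness_probability(expo[i], frac, params)
          st1 <- st; st1[i] <- 1
        } else {
          nadopt <- sum(st[nbrs[[i]]] == 2)
          frac <- if (deg[i] > 0) nadopt / deg[i] else 0
          p <- campaignsim::adoption_probability(agents$b_step[i], expo[i],
                                                 nadopt, frac, params)
          st1 <- st; st1[i] <- 2
        }
        if (p > 0) walk(st1, idx + 1, pr * p)
        if (p < 1) walk(st, idx + 1, pr * (1 - p))
      }
      walk(state, 1, 1)
    }
    out
  }

  # state distribution as named probabilities over state vectors
  dist <- setNames(1, paste(rep(0, n), collapse = ""))
  for (t in seq_len(params$horizon)) {
    for (phase in 1:2) {
      new <- new.env()
      for (key in names(dist)) {
        st <- as.integer(strsplit(key, "")[[1]])
        for (res in enum_phase(st, phase)) {
          k2 <- paste(res[[2]], collapse = "")
          new[[k2]] <- (if (is.null(new[[k2]])) 0 else new[[k2]]) + dist[[key]] * res[[1]]
        }
      }
      dist <- setNames(as.numeric(mget(ls(new), envir = new)), ls(new))
    }
  }
  sum(vapply(names(dist), function(key) {
    st <- as.integer(strsplit(key, "")[[1]])
    mean(st == 2) * dist[[key]]
  }, numeric(1)))
}
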