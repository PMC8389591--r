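# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use naive loops / enumeration and share
# no code with the package internals.

# step-up BH by explicit sort / scale / cumulative-min
naive_bh <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(n / (n:1) * p[o]))
    adj[ro]
}

# product-limit estimator via an explicit loop over distinct event times
naive_km <- function(times, events) {
    ev_times <- sort(unique(times[events == 1]))
    surv <- numeric(length(ev_times))
    n_risk <- integer(length(ev_times))
    n_event <- integer(length(ev_times))
    s <- 1
    for (i in seq_along(ev_times)) {
        t <- ev_times[i]
        n_risk[i] <- sum(times >= t)
        n_event[i] <- sum(times == t & events == 1)
        s <- s * (1 - n_event[i] / n_risk[i])
        surv[i] <- s
    }
    data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
        survival = surv)
}

# two-group log-rank via an explicit hypergeometric table per event time
naive_logrank <- function(ta, ea, tb, eb) {
    all_t <- sort(unique(c(ta[ea == 1], tb[eb == 1])))
    O1 <- E1 <- V <- 0
    for (t in all_t) {
        n1 <- sum(ta >= t); n2 <- sum(tb >= t); n <- n1 + n2
        d1 <- sum(ta == t & ea == 1); d2 <- sum(tb == t & eb == 1)
        d <- d1 + d2
        O1 <- O1 + d1
        E1 <- E1 + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
    }
    z <- (O1 - E1) / sqrt(V)
    list(obs_a = O1, exp_a = E1, var = V, z = z, chi2 = z^2,
        p = 2 * pnorm(-abs(z)))
}

# upper-tail hypergeometric p by direct combinatorial enumeration
enum_hypergeom_p <- function(overlap, set_size, query_size, universe_size) {
    ks <- overlap:min(set_size, query_size)
    sum(choose(set_size, ks) *
        choose(universe_size - set_size, query_size - ks)) /
        choose(universe_size, query_size)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# bivariate normal sample matrices: rows = replicates, cols = observations
bvn_cor_pairs <- function(n_rep, n_obs, rho) {
    x <- matrix(rnorm(n_rep * n_obs), n_rep, n_obs)
    e <- matrix(rnorm(n_rep * n_obs), n_rep, n_obs)
    y <- rho * x + sqrt(1 - rho^2) * e
    xs <- (x - rowMeans(x)) / sqrt(rowSums((x - rowMeans(x))^2))
    ys <- (y - rowMeans(y)) / sqrt(rowSums((y - rowMeans(y))^2))
    rowSums(xs * ys)
}

# WeightedNetwork fixture from an arbitrary weighted edge list (the
# correlation columns are placeholders; only D matters for detection)
make_weighted_net <- function(edges, n_long = 50L, n_short = 50L) {
    gx <- pmin(edges$gene_x, edges$gene_y)
    gy <- pmax(edges$gene_x, edges$gene_y)
    methods::new("WeightedNetwork",
        nodes = sort(unique(c(gx, gy))),
        edges = data.frame(gene_x = gx, gene_y = gy,
            r_L = 0, r_S = 0, z_L = 0, z_S = 0, D = edges$D,
            stringsAsFactors = FALSE),
        n_long = n_long, n_short = n_short)
}

# planted-partition weighted graph for module-recovery tests
planted_weighted_graph <- function(n_modules = 5L, size = 10L,
                                   p_in = 0.9, p_out = 0.02,
                                   w_in_mean = 3, w_in_sd = 0.5,
                                   w_out_mean = 0.3, w_out_sd = 0.1) {
    n <- n_modules * size
    genes <- sprintf("n%03d", seq_len(n))
    block <- rep(seq_len(n_modules), each = size)
    rows <- list()
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        same <- block[i] == block[j]
        if (runif(1) < (if (same) p_in else p_out)) {
            w <- if (same) abs(rnorm(1, w_in_mean, w_in_sd))
                else abs(rnorm(1, w_out_mean, w_out_sd))
            rows[[length(rows) + 1L]] <- data.frame(
                gene_x = genes[i], gene_y = genes[j], D = w,
                stringsAsFactors = FALSE)
        }
    }
    list(net = make_weighted_net(do.call(rbind, rows)),
        truth = split(genes, block))
}
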