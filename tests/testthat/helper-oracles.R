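# Shared fixtures and independent oracles, built in code.

make_net <- function(a, b, lls, nodes = character()) {
  gene_network(data.frame(a = a, b = b, lls = lls, stringsAsFactors = FALSE),
               nodes = nodes)
}

# star: center c linked to each spoke with the given lls values
star_net <- function(center = "hub", n_spokes, lls) {
  spokes <- sprintf("s%03d", seq_len(n_spokes))
  make_net(rep(center, n_spokes), spokes, rep_len(lls, n_spokes))
}

expect_same_network <- function(x, y) {
  expect_equal(network_nodes(x), network_nodes(y))
  expect_equal(network_edges(x), network_edges(y))
}

# Exhaustive one-sided (enrichment) hypergeometric tail, via choose():
# P(X >= k) for X ~ Hypergeom(N, K, n). Independent of stats::phyper.
hyper_tail_oracle <- function(k, K, N, n) {
  j <- seq(from = max(k, 0, K + n - N), to = min(K, n))
  if (!length(j) || k > min(K, n)) return(if (k <= max(0, K + n - N)) 1 else 0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Naive weighted-sum integration oracle: explicit per-pair collect/sort/sum.
naive_weighted_sum <- function(networks, D, T, decay_form = "geometric") {
  all_edges <- do.call(rbind, lapply(networks, network_edges))
  keys <- unique(paste(all_edges$a, all_edges$b, sep = "\r"))
  out <- list()
  for (key in keys) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    lls <- all_edges$lls[all_edges$a == parts[1] & all_edges$b == parts[2]]
    lls <- sort(lls[lls >= T], decreasing = TRUE)
    if (!length(lls)) next
    i <- seq_along(lls) - 1
    ws <- if (decay_form == "geometric") sum(lls / D^i)
          else lls[1] + sum(lls[-1] / (D * i[-1]))
    out[[key]] <- data.frame(a = parts[1], b = parts[2], lls = ws,
                             stringsAsFactors = FALSE)
  }
  nodes <- unique(unlist(lapply(networks, network_nodes)))
  gene_network(do.call(rbind, out), nodes = nodes)
}

# Direct-counting LLS oracle for binary evidence.
naive_binary_lls <- function(pos_e, neg_e, pos_tot, neg_tot, c = 1) {
  log(((pos_e + c) / (neg_e + c)) / ((pos_tot + c) / (neg_tot + c)))
}
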