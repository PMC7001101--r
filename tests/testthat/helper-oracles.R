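# Independent oracles: brute-force enumerators kept deliberately separate
# from the package's vectorized implementations.

# Exhaustive double-loop GLCM: walk every voxel, look at its displaced
# partner, count both directions, normalize.
oracle_glcm <- function(levels, ng, offset) {
  dims <- dim(levels)
  counts <- matrix(0, ng, ng)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    a <- levels[x, y, z]
    if (a == 0) next
    tx <- x + offset[1]; ty <- y + offset[2]; tz <- z + offset[3]
    if (tx < 1 || tx > dims[1] || ty < 1 || ty > dims[2] || tz < 1 || tz > dims[3]) next
    b <- levels[tx, ty, tz]
    if (b == 0) next
    counts[a, b] <- counts[a, b] + 1
    counts[b, a] <- counts[b, a] + 1
  }
  total <- sum(counts)
  list(p = if (total > 0) counts / total else counts, pair_count = total)
}

# Direct elementwise evaluation of every texture feature formula.
oracle_features <- function(p) {
  ng <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum((1:ng) * px); mu_y <- sum((1:ng) * py)
  sd_x <- sqrt(sum(((1:ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((1:ng) - mu_y)^2 * py))
  dis <- con <- ene <- ent <- ivar <- cor_n <- acor <- sha <- pro <- hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    con <- con + (i - j)^2 * pij
    dis <- dis + abs(i - j) * pij
    ene <- ene + pij^2
    if (pij > 0) ent <- ent - pij * log(pij)
    if (i != j) ivar <- ivar + pij / (i - j)^2
    cor_n <- cor_n + (i - mu_x) * (j - mu_y) * pij
    acor <- acor + i * j * pij
    sha <- sha + (i + j - mu_x - mu_y)^3 * pij
    pro <- pro + (i + j - mu_x - mu_y)^4 * pij
    if (px[i] * py[j] > 0) hxy2 <- hxy2 - px[i] * py[j] * log(px[i] * py[j])
  }
  corr <- if (sd_x * sd_y > 0) cor_n / (sd_x * sd_y) else NA_real_
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  c(Dissimilarity = dis, Contrast = con, Energy = ene, Entropy = ent,
    ClusterProminence = pro, ClusterShade = sha, InverseVariance = ivar,
    Correlation = corr, Autocorrelation = acor,
    InformationalMeasureCorrelation2 = imc2)
}

# Random small quantized VOI (direct construction of the container).
random_qvoi <- function(dims, ng) {
  lev <- array(sample(0:ng, prod(dims), replace = TRUE,
                      prob = c(0.3, rep(0.7 / ng, ng))),
               dim = dims)
  structure(list(levels = lev, n_levels = as.integer(ng), range = c(0, 1),
                 spacing_mm = c(1, 1, 1)),
            class = "quantized_voi")
}

make_qvoi <- function(levels, ng) {
  structure(list(levels = levels, n_levels = as.integer(ng), range = c(0, 1),
                 spacing_mm = c(1, 1, 1)),
            class = "quantized_voi")
}

make_glcm <- function(p, pair_count = 100L) {
  structure(list(p = p, offset = c(1L, 0L, 0L), pair_count = as.integer(pair_count),
                 n_levels = nrow(p)), class = "glcm")
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(nA + nB, nA) group assignments (no ties assumed).
oracle_mw_exact <- function(a, b) {
  pool <- c(a, b)
  n_a <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) # no ties
  u_obs <- u_of(a, b)
  idx <- utils::combn(length(pool), n_a)
  us <- apply(idx, 2, function(ii) u_of(pool[ii], pool[-ii]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Concordance AUC by explicit pair enumeration, ties credited 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# Minimal long feature table for group-comparison simulations.
sim_feature_table <- function(values_by_feature, modality = "ADC") {
  n <- length(values_by_feature[[1]])
  df <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                   modality = modality, stringsAsFactors = FALSE)
  for (fn in names(values_by_feature)) df[[fn]] <- values_by_feature[[fn]]
  df
}
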