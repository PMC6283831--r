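# Small factor catalogues and simulation configs reused across tests.

# k quantitative toy factors mapped to valid MIEO categories
toy_factors <- function(k) {
  cats <- rep(c("Media components", "Container geometry", "Environment",
                "Time", "Inoculum"), length.out = k)
  specs <- lapply(seq_len(k), function(i) {
    factor_spec(paste0("f", i), cats[i], "quantitative",
                low = 0, high = 2, center = 1, units = "u")
  })
  stats::setNames(specs, paste0("f", seq_len(k)))
}

# noise-free config pricing only the named coefficients on toy factors
toy_config <- function(dcm_beta = numeric(0), titer_beta = numeric(0),
                       dcm_inter = numeric(0), titer_inter = numeric(0),
                       baseline = c(dry_cell_mass = 8, titer = 8.5),
                       noise_cv = c(dry_cell_mass = 0, titer = 0),
                       day_sd = c(dry_cell_mass = 0, titer = 0),
                       month_sd = c(dry_cell_mass = 0, titer = 0)) {
  simulation_config(
    baseline = baseline,
    main_effects = list(dry_cell_mass = dcm_beta, titer = titer_beta),
    interactions = list(dry_cell_mass = dcm_inter, titer = titer_inter),
    noise_cv = noise_cv, day_sd = day_sd, month_sd = month_sd)
}

# simulate quietly when toy factors are deliberately unpriced
sim_quiet <- function(...) suppressWarnings(simulate_responses(...))

# brute-force alias groups: compare all column products of the coded matrix
brute_force_aliases <- function(design, max_order = 2L) {
  X <- design_matrix(design)
  facs <- colnames(X)
  k <- length(facs)
  effects <- c(lapply(seq_len(k), function(i) i),
               utils::combn(seq_len(k), 2L, simplify = FALSE))
  cols <- lapply(effects, function(idx) {
    apply(X[, idx, drop = FALSE], 1, prod)
  })
  labels <- vapply(effects, function(idx) paste(facs[idx], collapse = ":"),
                   character(1))
  out <- lapply(seq_along(effects), function(i) {
    same <- vapply(seq_along(effects), function(j) {
      all(cols[[i]] == cols[[j]]) || all(cols[[i]] == -cols[[j]])
    }, logical(1))
    sort(labels[same & seq_along(effects) != i])
  })
  stats::setNames(out, labels)
}

# letters-to-factor-name translation of an alias_structure's groups
alias_groups_as_names <- function(alias, facs) {
  name_of <- stats::setNames(facs, alias$letters)
  out <- lapply(alias$alias_groups, function(group) {
    sort(vapply(group, function(w) {
      paste(name_of[strsplit(w, "")[[1]]], collapse = ":")
    }, character(1), USE.NAMES = FALSE))
  })
  keys <- vapply(names(alias$alias_groups), function(w) {
    paste(name_of[strsplit(w, "")[[1]]], collapse = ":")
  }, character(1), USE.NAMES = FALSE)
  stats::setNames(out, keys)
}
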