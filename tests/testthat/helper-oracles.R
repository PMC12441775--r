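# Independent oracles used across test files.

# all permutations of 1:k (k small)
perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# exhaustive-enumeration two-sided p-value for the rank-sum difference of
# treatments 1 and 2 over n blocks of k treatments: all (k!)^n joint
# rankings equally likely
enum_pair_pvalue <- function(D, n, k) {
  pm <- perms(k)
  d1 <- pm[, 1L] - pm[, 2L]          # per-block differences, k! outcomes
  tot <- d1
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      tot <- as.vector(outer(tot, d1, `+`))
    }
  }
  mean(abs(tot) >= abs(D))
}

# random community of 2..12 species with log-normal abundances
random_community <- function() {
  s <- sample(2:12, 1L)
  p <- rlnorm(s, 0, 1.2)
  setNames(p, paste0("SP", seq_len(s)))
}

# small structural config with every path family equal across groups
# except those supplied in `vary`
shared_config <- function(vary = character(0)) {
  std <- list(
    a = c(DSSstd = -0.18, DSSred = -0.18, AdvLoc = -0.18, AdvSer = -0.18),
    b = c(DSSstd = 0.45, DSSred = 0.45, AdvLoc = 0.45, AdvSer = 0.45),
    c = c(DSSstd = -0.28, DSSred = -0.28, AdvLoc = -0.28, AdvSer = -0.28),
    d = c(DSSstd = 0.31, DSSred = 0.31, AdvLoc = 0.31, AdvSer = 0.31),
    e = c(DSSstd = 0.45, DSSred = 0.45, AdvLoc = 0.45, AdvSer = 0.45),
    f = c(DSSstd = 0.54, DSSred = 0.54, AdvLoc = 0.54, AdvSer = 0.54))
  defaults <- weedpath:::.default_std_coef
  for (nm in vary) std[[nm]] <- defaults[[nm]]
  trial_config(std_coef = std,
               tfi_mean = 1.3, dsum_mean = 9)
}
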