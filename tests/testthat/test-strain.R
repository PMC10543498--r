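test_that("alignment log-likelihood matches the closed form", {
  set.seed(61)
  genomes <- simulateStrainGenomes(2, genomeLength = 20000, seed = 61)
  panel <- strainPanel(genomes)
  eps <- 0.01
  g1 <- genomes[[1]]
  read <- substring(g1, 501, 650)
  # introduce exactly one mismatch vs strain 1
  ch <- strsplit(read, "")[[1]]
  ch[75] <- setdiff(c("A", "C", "G", "T"), ch[75])[1]
  read1mm <- paste(ch, collapse = "")
  grp <- new("BarcodeGroup", barcodeId = "t",
             mate1 = read1mm, mate2 = strrep("N", 150),
             qual1 = "I", qual2 = "I", batch = "single_cell", truth = NULL,
             truthHost = NA_character_, truthContamination = NA_real_)
  lik <- alignReadsToPanel(grp, panel, epsilon = eps, seedStep = 1L)
  expected <- 1 * log(eps / 3) + 149 * log(1 - eps)
  expect_equal(lik@logLik[1, 1], expected, tolerance = 1e-12)
  expect_error(alignReadsToPanel(grp, panel, epsilon = 0.3), "epsilon")
})

test_that("reads from identical shared regions score equally across
           strains; strain-unique reads hit only their strain", {
  base <- generateGenome(20000, seed = 62)
  # strain 2 differs only in its second half
  s2 <- paste0(substring(base, 1, 10000),
               mutateGenome(substring(base, 10001, 20000), 0.02, seed = 63))
  panel <- strainPanel(c(strain01 = base, strain02 = s2))
  sharedRead <- substring(base, 1001, 1150)
  grp <- function(r) new("BarcodeGroup", barcodeId = "t", mate1 = r,
                         mate2 = strrep("N", 150), qual1 = "I", qual2 = "I",
                         batch = "single_cell", truth = NULL,
                         truthHost = NA_character_,
                         truthContamination = NA_real_)
  likS <- alignReadsToPanel(grp(sharedRead), panel, seedStep = 1L)
  expect_equal(likS@logLik[1, 1], likS@logLik[1, 2])
  # a read overlapping enough divergent sites is unique to its strain at
  # the default mismatch cap: scan the mutated half for a window with > 5
  # mismatches (one must exist at 2% divergence over 10 kb)
  diffs <- which(strsplit(substring(base, 10001, 20000), "")[[1]] !=
                 strsplit(substring(s2, 10001, 20000), "")[[1]])
  starts <- 10000 + seq(1, 9850, by = 50)
  mm <- vapply(starts, function(s)
    sum(diffs >= (s - 10000) & diffs <= (s - 10000 + 149)), integer(1))
  w <- starts[which(mm > 5)[1]]
  expect_false(is.na(w))
  uniq <- substring(base, w, w + 149)
  likU <- alignReadsToPanel(grp(uniq), panel, seedStep = 1L)
  expect_true(is.finite(likU@logLik[1, 1]))
  expect_identical(likU@logLik[1, 2], -Inf)
})

test_that("estimateAbundanceVB recovers degenerate and symmetric cases", {
  n <- 1000
  # all reads unique to strain 1
  ll <- matrix(-Inf, n, 3, dimnames = list(NULL, paste0("s", 1:3)))
  ll[, 1] <- -1
  lik <- new("AlignmentLikelihoods", barcodeId = "t", logLik = ll,
             readIds = as.character(1:n))
  post <- estimateAbundanceVB(lik)
  expect_gt(post@theta[["s1"]], 0.99)
  expect_equal(sum(post@theta), 1, tolerance = 1e-12)
  # perfectly ambiguous two-strain reads -> (0.5, 0.5)
  ll2 <- matrix(-2, 200, 2, dimnames = list(NULL, c("a", "b")))
  lik2 <- new("AlignmentLikelihoods", barcodeId = "t", logLik = ll2,
              readIds = as.character(1:200))
  post2 <- estimateAbundanceVB(lik2)
  expect_equal(unname(post2@theta), c(0.5, 0.5), tolerance = 1e-9)
  expect_identical(post2@nInformativeReads, 0L)
})

test_that("VB matches a brute-force EM oracle on random likelihood
           matrices", {
  # random matrices with the structure the aligner emits: per-(read, strain)
  # mismatch counts in 0..5, so reads range from strain-specific to fully
  # ambiguous; the VB side uses the oracle's uniform prior
  set.seed(64)
  eps <- 0.01
  for (rep in 1:10) {
    m <- matrix(sample(0:5, 200 * 4, replace = TRUE), 200, 4,
                dimnames = list(NULL, paste0("s", 1:4)))
    logL <- m * log(eps / 3) + (150 - m) * log(1 - eps)
    lik <- new("AlignmentLikelihoods", barcodeId = "t", logLik = logL,
               readIds = as.character(1:200))
    vb <- estimateAbundanceVB(lik, alpha = 1)
    em <- oracleEm(exp(logL - apply(logL, 1, max)), iters = 10000L)
    expect_lt(max(abs(vb@theta - em)), 2e-3)
  }
})

test_that("ELBO trace is monotone non-decreasing and theta stays on the
           simplex", {
  set.seed(65)
  for (rep in 1:5) {
    L <- matrix(runif(100 * 3, 0.01, 1), 100, 3,
                dimnames = list(NULL, paste0("s", 1:3)))
    lik <- new("AlignmentLikelihoods", barcodeId = "t", logLik = log(L),
               readIds = as.character(1:100))
    post <- estimateAbundanceVB(lik)
    expect_true(all(diff(post@elbo) > -1e-8))
    expect_true(all(post@theta >= 0))
    expect_equal(sum(post@theta), 1, tolerance = 1e-12)
  }
})

test_that("permuting the strain panel permutes theta identically", {
  set.seed(66)
  L <- matrix(runif(150 * 4, 0.01, 1), 150, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  lik <- new("AlignmentLikelihoods", barcodeId = "t", logLik = log(L),
             readIds = as.character(1:150))
  perm <- c(3, 1, 4, 2)
  likP <- new("AlignmentLikelihoods", barcodeId = "t",
              logLik = log(L)[, perm], readIds = as.character(1:150))
  th <- estimateAbundanceVB(lik)@theta
  thP <- estimateAbundanceVB(likP)@theta
  expect_equal(unname(thP), unname(th[perm]), tolerance = 1e-9)
  expect_identical(names(thP), names(th)[perm])
})

test_that("assignStrain applies the 15% maximum-abundance rule with ties
           going to mixed", {
  mkPost <- function(theta) new("StrainPosterior",
    theta = setNames(theta, paste0("s", seq_along(theta))),
    elbo = 0, converged = TRUE, nInformativeReads = 1L,
    assignment = NA_character_)
  expect_identical(strainAssignment(assignStrain(mkPost(c(0.9, 0.05, 0.05)))),
                   "s1")
  # 22-strain group with max below 0.15 -> mixed
  th22 <- c(0.14, rep(0.86 / 21, 21))
  expect_identical(strainAssignment(assignStrain(mkPost(th22))), "mixed")
  # exactly at the threshold is assigned
  expect_identical(strainAssignment(assignStrain(mkPost(c(0.15,
    rep(0.85 / 21, 21))))), "s1")
  expect_identical(strainAssignment(assignStrain(mkPost(c(0.5, 0.5)))),
                   "mixed")
})

test_that("likelihoodsFromSam builds the matrix from NM tags", {
  sam <- tempfile(fileext = ".sam")
  rec <- function(q, ref, nm) paste(q, "0", ref, "100", "42", "150M", "*",
                                    "0", "0", strrep("A", 150),
                                    strrep("I", 150), paste0("NM:i:", nm),
                                    sep = "\t")
  writeLines(c("@HD\tVN:1.6", rec("r1", "sA", 0), rec("r1", "sB", 3),
               rec("r2", "sA", 1)), sam)
  lik <- likelihoodsFromSam(readSamSubset(sam), c("sA", "sB"),
                            epsilon = 0.01)
  expect_identical(dim(lik@logLik), c(2L, 2L))
  expect_equal(lik@logLik["r1", "sA"], 150 * log(0.99), tolerance = 1e-12)
  expect_equal(lik@logLik["r1", "sB"],
               3 * log(0.01 / 3) + 147 * log(0.99), tolerance = 1e-12)
  expect_identical(lik@logLik["r2", "sB"], -Inf)
})

test_that("single-strain barcodes are assigned to their strain and read
           depth does not hurt accuracy", {
  genomes <- simulateStrainGenomes(4, genomeLength = 50000,
                                   divergence = 0.01, seed = 67)
  refset <- strainRefset(genomes)
  panel <- strainPanel(genomes)
  callOne <- function(host, nPairs, seed) {
    g <- simulateBarcodeGroup(refset, host,
      simulationConfig(contaminationRange = c(0, 0)), seed = seed,
      nPairs = nPairs)
    lik <- alignReadsToPanel(g, panel)
    strainAssignment(assignStrain(estimateAbundanceVB(lik)))
  }
  hosts <- rep(names(genomes), each = 5)
  callsLow <- vapply(seq_along(hosts), function(i)
    callOne(hosts[i], 200L, i), character(1))
  callsHigh <- vapply(seq_along(hosts), function(i)
    callOne(hosts[i], 1000L, 100 + i), character(1))
  accLow <- mean(callsLow == hosts)
  accHigh <- mean(callsHigh == hosts)
  expect_gte(accHigh, accLow)
  expect_gte(accHigh, 0.95)
})
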