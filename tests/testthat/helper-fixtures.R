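# Shared fixtures: built in code, deterministic.

# toy 2-position scorer from rounded log-probabilities
toy_table <- function() {
  m <- matrix(c(-0.1, -2.4,
                -1.0, -0.5), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("A", "C")))
  m
}

toy_scorer2 <- function(id = "toy1") gen_toy_scorer(toy_table(), id = id)

# random normalized toy scorer over a small alphabet
random_scorer <- function(len, alphabet = c("A", "C", "D", "E"), seed = 1) {
  set.seed(seed)
  p <- matrix(rexp(len * length(alphabet)), len)
  p <- p / rowSums(p)
  tab <- log(p)
  colnames(tab) <- alphabet
  gen_toy_scorer(tab, id = paste0("rand", seed))
}

# an ideal antiparallel two-strand hairpin (frozen placement: the second
# strand is the first rotated 180 degrees and offset so that cross-strand
# hydrogen bonds form; turn residues 7-8 are placed apart as loop)
make_hairpin_traj <- function() {
  s1 <- haplodyn:::build_backbone(rep(-139, 6), rep(135, 6))
  idx <- function(res, atom) {
    n1 <- c("N", "CA", "C", "O")
    n2 <- c("N", "H", "CA", "C", "O")
    if (res == 1) which(n1 == atom) else 4 + (res - 2) * 5 + which(n2 == atom)
  }
  cas <- t(sapply(1:6, function(r) s1[idx(r, "CA"), ]))
  u <- cas[6, ] - cas[1, ]; u <- u / sqrt(sum(u^2))
  z <- c(0, 0, 1); n1 <- z - sum(z * u) * u; n1 <- n1 / sqrt(sum(n1^2))
  w <- c(n1[2] * u[3] - n1[3] * u[2], n1[3] * u[1] - n1[1] * u[3],
         n1[1] * u[2] - n1[2] * u[1])
  center <- colMeans(cas)
  a <- n1
  s2 <- sweep(s1, 2, center)
  s2 <- t(apply(s2, 1, function(v) 2 * sum(a * v) * a - v))
  s2 <- sweep(s2, 2, center, "+")
  s2 <- sweep(s2, 2, 3.6 * w + (-3.5) * u, "+")
  coords <- NULL; resid <- c(); aname <- c()
  add <- function(r, nm, xyz) {
    coords <<- rbind(coords, xyz); resid <<- c(resid, r)
    aname <<- c(aname, nm)
  }
  for (r in 1:6) for (nm in c("N", "H", "CA", "C", "O")) {
    if (!(r == 1 && nm == "H")) add(r, nm, s1[idx(r, nm), ])
  }
  add(7, "N", c(50, 50, 50)); add(7, "H", c(50, 49.2, 50))
  add(7, "CA", c(51.4, 50, 50)); add(7, "C", c(52, 51.2, 50))
  add(7, "O", c(53.2, 51.2, 50))
  add(8, "N", c(55, 55, 55)); add(8, "H", c(55, 54.2, 55))
  add(8, "CA", c(56.4, 55, 55)); add(8, "C", c(57, 56.2, 55))
  add(8, "O", c(58.2, 56.2, 55))
  for (r in 6:1) {
    rb <- 15 - r
    for (nm in c("N", "H", "CA", "C", "O")) {
      if (!(r == 1 && nm == "H")) add(rb, nm, s2[idx(r, nm), ])
    }
  }
  topo <- tibble::tibble(resid = resid, resname = "ALA", atom = aname,
                         element = substr(aname, 1, 1))
  md_trajectory(coords, topo)
}

# run mdtraj's simplified DSSP (independent reference implementation) on a
# trajectory; returns a character matrix with H/E/C codes
mdtraj_dssp <- function(traj) {
  pdb <- tempfile(fileext = ".pdb")
  on.exit(unlink(pdb))
  write_trajectory_pdb(traj, pdb)
  script <- sprintf(
    "import mdtraj as md\nimport sys\nt = md.load('%s')\nss = md.compute_dssp(t, simplified=True)\nfor row in ss: print(''.join(row))",
    pdb)
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = FALSE))
  do.call(rbind, strsplit(out, ""))
}

# tiny hand-built frame factory: place named atoms of named residues
frame_from_atoms <- function(df) {
  md_trajectory(as.matrix(df[, c("x", "y", "z")]),
                tibble::tibble(resid = df$resid, resname = df$resname,
                               atom = df$atom,
                               element = df$element %||%
                                 substr(df$atom, 1, 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
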