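## Authors the packaged reference network configuration
## (inst/extdata/pdac_network.yaml) plus the initial-condition tables
## (inst/extdata/ic_bounds.csv, validated_ic.csv).
##
## The network is a reconstruction: 46 dynamic metabolites and 53 reactions
## spanning glycolysis, the PPP, glutaminolysis, the TCA cycle and the
## mitochondrial shuttles, with rate laws in the style of the published
## HeLa-glycolysis / CHO-TCA/PPP kinetic models. Maximal velocities are
## calibrated here so that, at the validated baseline initial condition
## (IC #1), every reaction carries a hand-balanced target flux (S v ~ 0 for
## the dynamic species), giving a quasi-steady baseline from which protocol
## perturbations (knockdowns, media switches) unfold.
##
## Run from the repository root:  Rscript data-raw/build_network.R

source("R/ratelaws.R")

## ---------------------------------------------------------------- species
## baseline = validated IC #1 (Table of validated initial conditions)
ic1 <- c(
  GLC = 14,     ATP = 7.7,    G6P = 1.2,    ADP = 1.9,   F6P = 0.21,
  FBP = 0.10,   DHAP = 0.88,  G3P = 0.57,   NAD = 0.31,  `13BPG` = 0.0067,
  `3PG` = 0.34, `2PG` = 0.049, PEP = 0.054, PYR = 8.1,   LAC = 19,
  AMP = 0.25,   `6PG` = 0.0045, Ru5P = 0.027, Xyl5P = 0.013, R5P = 0.014,
  E4P = 0.18,   S7P = 0.057,  NADP = 0.38,  NADPH = 0.0056, NADH = 0.061,
  GSH = 2.1,    GSSG = 0.32,  GLN = 4.3,    GLU = 2.8,   ASP = 7.0,
  OAA = 1.2,    MAL = 1.9,    AKG = 0.0061, CIT = 0.51,
  mPYR = 7.9,   mAcCoA = 0.12, mCIT = 0.098, mICIT = 0.017, mAKG = 0.020,
  mSCoA = 0.72, mSUC = 2.5,   mFUM = 0.16,  mMAL = 1.2,  mOAA = 1.9,
  mASP = 4.3,   mGLU = 2.0)

ic2 <- c(
  GLC = 3.1,    ATP = 9.9,    G6P = 1.8,    ADP = 1.0,   F6P = 0.028,
  FBP = 0.38,   DHAP = 0.77,  G3P = 0.044,  NAD = 0.81,  `13BPG` = 0.014,
  `3PG` = 0.099, `2PG` = 0.045, PEP = 0.21, PYR = 4.4,   LAC = 63,
  AMP = 1.3,    `6PG` = 0.0094, Ru5P = 0.076, Xyl5P = 0.013, R5P = 0.006,
  E4P = 0.052,  S7P = 0.071,  NADP = 0.072, NADPH = 0.033, NADH = 0.0097,
  GSH = 3.1,    GSSG = 0.91,  GLN = 5.5,    GLU = 3.2,   ASP = 6.7,
  OAA = 1.2,    MAL = 2.1,    AKG = 0.021,  CIT = 0.17,
  mPYR = 6.9,   mAcCoA = 0.10, mCIT = 0.50, mICIT = 0.0249, mAKG = 0.0157,
  mSCoA = 1.5,  mSUC = 1.8,   mFUM = 0.16,  mMAL = 2.2,  mOAA = 1.7,
  mASP = 3.2,   mGLU = 0.30)

fixed <- c(mATP = 3.0, mADP = 1.5, mNAD = 0.5, mNADH = 0.05,
           Pi = 2.5, mPi = 5.0, F26BP = 0.005)
boundary <- c(GLC_e = 35, GLN_e = 6, LAC_e = 1.0, ALA_e = 0.1)

conc <- c(ic1, fixed, boundary)

mito_dyn <- c("mPYR", "mAcCoA", "mCIT", "mICIT", "mAKG", "mSCoA", "mSUC",
              "mFUM", "mMAL", "mOAA", "mASP", "mGLU")
lhs_copy <- c(mPYR = "PYR", mCIT = "CIT", mAKG = "AKG", mMAL = "MAL",
              mOAA = "OAA", mASP = "ASP", mGLU = "GLU")

species <- lapply(names(ic1), function(id) {
  s <- list(id = id,
            compartment = if (id %in% mito_dyn) "mitochondria" else "cytosol",
            type = "dynamic", conc = unname(ic1[[id]]),
            pool = sub("^m", "", id))
  if (id %in% names(lhs_copy)) s$lhs_copy_of <- lhs_copy[[id]]
  s
})
species <- c(species,
  lapply(names(fixed), function(id)
    list(id = id, compartment = if (startsWith(id, "m")) "mitochondria" else "cytosol",
         type = "fixed", conc = unname(fixed[[id]]), pool = sub("^m", "", id))),
  lapply(names(boundary), function(id)
    list(id = id, compartment = "extracellular", type = "boundary",
         conc = unname(boundary[[id]]), pool = id)))

## ------------------------------------------------------------- reactions
## Hand-balanced target fluxes (mM/min) at the baseline state; see the
## methods vignette for the balance bookkeeping.
phi <- c(
  GLUT1 = 0.05, HK = 0.05, PGI = 0.045, PFK = 0.048267, ALD = 0.048267,
  TPI = 0.048267, GAPDH = 0.098167, PGK = 0.098167, PGAM = 0.098167,
  ENO = 0.098167, PK = 0.098167, LDH = 0.058167, MCT = 0.058167,
  ATPASE = 0.267107, AK = -4e-05, AMPD = 2.4e-04,
  G6PDH = 0.005, PGDH = 0.005, RPE = 0.003267, RPI = 0.001733,
  TKT1 = 0.001633, TALDO = 0.001633, TKT2 = 0.001633, PRPPS = 2e-04,
  GSSGR = 0.025, GPX = 0.025, NADPHOX = 0.0222, NADHSH = 0.003,
  GLNT = 0.035, GLS = 0.035, GLUD1 = 2e-04, GOT1 = 0.036, GOT2 = 0.0358,
  GPT = 0.035, ME1 = 0.0372, MDH1 = 0.037, MDH2 = 0.0627,
  FUM = 0.0742, SDH = 0.0742, SCS = 0.0742, AKGDH = 0.0742,
  IDH = 0.0392, ACO = 0.0392, CS = 0.0402, PDH = 0.0402, PC = 0.002,
  MPC = 0.0422, MALAKG = 0.001, ASPGLU = 0.036, CITMAL = 0.001,
  MALPi = 0.0022, ACL = 0.001, OXPHOS = 0.17)

## shorthand modifier constructors
I <- function(sp) list(type = "inh", species = sp)
A <- function(sp) list(type = "act", species = sp)
K <- function(sp) list(type = "cof", species = sp)
AI <- function(sp) list(type = "allo_inh", species = sp)
AA <- function(sp) list(type = "allo_act", species = sp)

rx_def <- list(
 ## ---- glycolysis / cytosolic energetics ----
 list(id="GLUT1", pathway="glycolysis", form="carrier", akt=TRUE, excess=10,
      st=c(GLC_e=-1, GLC=1), subs="GLC_e", pros="GLC", keq=1,
      mods=list(I("LAC"))),
 list(id="HK", pathway="glycolysis", form="mm_irr", akt=TRUE, r=NA,
      st=c(GLC=-1, ATP=-1, G6P=1, ADP=1), subs=c("GLC","ATP"), pros=c("G6P","ADP"),
      km=c(Km_GLC=0.1, Km_ATP=0.3, Ki_ADP=30, Ki_AMP=30), mods=list(I("G6P"), I("13BPG"), I("ADP"), I("AMP"))),
 list(id="PGI", pathway="glycolysis", form="mm_rev", r=1.05,
      st=c(G6P=-1, F6P=1), subs="G6P", pros="F6P",
      mods=list(I("6PG"), I("E4P"), I("FBP"))),
 list(id="PFK", pathway="glycolysis", form="mwc", akt=TRUE,
      st=c(F6P=-1, ATP=-1, FBP=1, ADP=1), subs=c("F6P","ATP"), pros=c("FBP","ADP"),
      mwc=c(n=2, L0=2, c=0.01), km=c(Km_ATP=0.2),
      mods=list(AA("AMP"), AA("ADP"), AA("F26BP"), A("Pi"),
                AI("ATP"), AI("CIT"), AI("LAC"))),
 list(id="ALD", pathway="glycolysis", form="haldane", r=1.2,
      st=c(FBP=-1, DHAP=1, G3P=1), subs="FBP", pros=c("DHAP","G3P"),
      km=c(Ki_ADP=30, Ki_AMP=30), mods=list(I("ADP"), I("AMP"))),
 list(id="TPI", pathway="glycolysis", form="mm_rev", r=1.05,
      st=c(DHAP=-1, G3P=1), subs="DHAP", pros="G3P",
      mods=list(I("PEP"), I("3PG"))),
 list(id="GAPDH", pathway="glycolysis", form="bibi_rev", r=3,
      st=c(G3P=-1, NAD=-1, `13BPG`=1, NADH=1),
      subs=c("G3P","NAD"), pros=c("13BPG","NADH"),
      mods=list(K("Pi"), I("ATP"))),
 list(id="PGK", pathway="glycolysis", form="bibi_rev", r=3,
      st=c(`13BPG`=-1, ADP=-1, `3PG`=1, ATP=1),
      subs=c("13BPG","ADP"), pros=c("3PG","ATP"),
      km=c(Ki_AMP=30), mods=list(I("AMP"))),
 list(id="PGAM", pathway="glycolysis", form="mm_rev", r=1.05,
      st=c(`3PG`=-1, `2PG`=1), subs="3PG", pros="2PG", mods=list(I("PEP"))),
 list(id="ENO", pathway="glycolysis", form="mm_rev", r=1.05,
      st=c(`2PG`=-1, PEP=1), subs="2PG", pros="PEP", mods=list(I("Pi"))),
 list(id="PK", pathway="glycolysis", form="mwc",
      st=c(PEP=-1, ADP=-1, PYR=1, ATP=1), subs=c("PEP","ADP"), pros=c("PYR","ATP"),
      mwc=c(n=2, L0=1, c=0.01),
      mods=list(AA("FBP"), AI("ATP"), AI("CIT"), AI("ALA_e"))),
 list(id="LDH", pathway="glycolysis", form="bibi_rev", r=3,
      st=c(PYR=-1, NADH=-1, LAC=1, NAD=1),
      subs=c("PYR","NADH"), pros=c("LAC","NAD"), mods=list(I("ATP"))),
 list(id="MCT", pathway="glycolysis", form="carrier", keq=1,
      st=c(LAC=-1, LAC_e=1), subs="LAC", pros="LAC_e", mods=list(I("PYR"))),
 list(id="ATPASE", pathway="energetics", form="mm_irr",
      st=c(ATP=-1, ADP=1), subs="ATP", pros="ADP",
      km=c(Km_ATP=2, Ki_AMP=3), mods=list(I("ADP"), I("AMP"))),
 list(id="AK", pathway="energetics", form="ma_rev",
      st=c(ATP=-1, AMP=-1, ADP=2), subs=c("ATP","AMP"), pros="ADP"),
 ## ---- pentose phosphate pathway ----
 list(id="G6PDH", pathway="ppp", form="mm_irr",
      st=c(G6P=-1, NADP=-1, `6PG`=1, NADPH=1), subs=c("G6P","NADP"),
      pros=c("6PG","NADPH"),
      mods=list(I("NADPH"), I("ATP"), I("6PG"), I("NADH"))),
 list(id="PGDH", pathway="ppp", form="mm_irr",
      st=c(`6PG`=-1, NADP=-1, Ru5P=1, NADPH=1), subs=c("6PG","NADP"),
      pros=c("Ru5P","NADPH"), mods=list(I("NADPH"), I("Ru5P"), I("ATP"))),
 list(id="RPE", pathway="ppp", form="mm_rev", r=1.05,
      st=c(Ru5P=-1, Xyl5P=1), subs="Ru5P", pros="Xyl5P", mods=list(I("6PG"))),
 list(id="RPI", pathway="ppp", form="mm_rev", r=1.05,
      st=c(Ru5P=-1, R5P=1), subs="Ru5P", pros="R5P", mods=list(I("6PG"))),
 list(id="TKT1", pathway="ppp", form="bibi_rev", r=1.05,
      st=c(R5P=-1, Xyl5P=-1, S7P=1, G3P=1),
      subs=c("R5P","Xyl5P"), pros=c("S7P","G3P")),
 list(id="TALDO", pathway="ppp", form="bibi_rev", r=1.05,
      st=c(S7P=-1, G3P=-1, E4P=1, F6P=1),
      subs=c("S7P","G3P"), pros=c("E4P","F6P")),
 list(id="TKT2", pathway="ppp", form="bibi_rev", r=1.05,
      st=c(Xyl5P=-1, E4P=-1, F6P=1, G3P=1),
      subs=c("Xyl5P","E4P"), pros=c("F6P","G3P")),
 list(id="PRPPS", pathway="ppp", form="mm_irr",
      st=c(R5P=-1, ATP=-1, AMP=1), subs=c("R5P","ATP"), pros="AMP",
      km=c(Ka_GSSG=2), mods=list(A("GSSG"))),
 ## ---- redox ----
 list(id="GSSGR", pathway="redox", form="mm_irr",
      st=c(GSSG=-1, NADPH=-1, GSH=2, NADP=1), subs=c("GSSG","NADPH"),
      pros=c("GSH","NADP"), km=c(Km_GSSG=0.05, Km_NADPH=0.02),
      mods=list(I("GSH"), I("NADP"), I("NADH"))),
 list(id="GPX", pathway="redox", form="mm_irr",
      st=c(GSH=-2, GSSG=1), subs="GSH", pros="GSSG",
      km=c(Km_GSH=0.1, Ki_GSSG=30), mods=list(I("GSSG"))),
 list(id="NADPHOX", pathway="redox", form="mm_irr",
      st=c(NADPH=-1, NADP=1), subs="NADPH", pros="NADP",
      km=c(Km_NADPH=5e-4), mods=list(I("NADP"), I("NADH"))),
 list(id="NADHSH", pathway="redox", form="mm_irr",
      st=c(NADH=-1, NAD=1), subs="NADH", pros="NAD",
      mods=list(I("NAD"), I("NADPH"))),
 list(id="AMPD", pathway="energetics", form="mm_irr",
      st=c(AMP=-1), subs="AMP", pros=character(0),
      km=c(Km_AMP=0.3, Ka_ATP=10), mods=list(A("ATP"), I("Pi"))),
 ## ---- glutaminolysis / transaminases ----
 list(id="GLNT", pathway="glutaminolysis", form="carrier", keq=1, excess=3,
      st=c(GLN_e=-1, GLN=1), subs="GLN_e", pros="GLN", mods=list(I("ALA_e"))),
 list(id="GLS", pathway="glutaminolysis", form="mwc",
      st=c(GLN=-1, GLU=1), subs="GLN", pros="GLU",
      mwc=c(n=2, L0=5, c=0.01), mods=list(A("Pi"), I("GLU"))),
 list(id="GLUD1", pathway="glutaminolysis", form="mm_irr",
      st=c(mGLU=-1, mAKG=1), subs="mGLU", pros="mAKG",
      mods=list(K("mNAD"), A("mADP"), I("mNADH"), I("mAKG"))),
 list(id="GOT1", pathway="glutaminolysis", form="haldane", r=10, kmfac=0.2,
      st=c(ASP=-1, AKG=-1, OAA=1, GLU=1), subs=c("ASP","AKG"),
      pros=c("OAA","GLU"), km=c(Km_OAA=6, Km_GLU=14),
      mods=list(I("ALA_e"))),
 list(id="GOT2", pathway="glutaminolysis", form="haldane", r=10, kmfac=0.2,
      st=c(mOAA=-1, mGLU=-1, mASP=1, mAKG=1), subs=c("mOAA","mGLU"),
      pros=c("mASP","mAKG"), km=c(Km_mASP=21.5, Km_mAKG=0.1),
      mods=list(I("mMAL"))),
 list(id="GPT", pathway="glutaminolysis", form="haldane", r=3,
      st=c(GLU=-1, PYR=-1, AKG=1, ALA_e=1), subs=c("GLU","PYR"),
      pros=c("AKG","ALA_e"), mods=list(I("ASP"))),
 list(id="ME1", pathway="glutaminolysis", form="mm_irr",
      st=c(MAL=-1, NADP=-1, PYR=1, NADPH=1), subs=c("MAL","NADP"),
      pros=c("PYR","NADPH"), km=c(Km_MAL=3.0),
      mods=list(I("NADPH"), I("ATP"))),
 list(id="MDH1", pathway="glutaminolysis", form="bibi_rev", r=3,
      st=c(OAA=-1, NADH=-1, MAL=1, NAD=1), subs=c("OAA","NADH"),
      pros=c("MAL","NAD"), mods=list(I("ATP"))),
 ## ---- TCA cycle ----
 list(id="MDH2", pathway="tca", form="bibi_rev", r=1.05,
      st=c(mMAL=-1, mNAD=-1, mOAA=1, mNADH=1), subs=c("mMAL","mNAD"),
      pros=c("mOAA","mNADH"), mods=list(I("mATP"))),
 list(id="FUM", pathway="tca", form="mm_rev", r=1.05,
      st=c(mFUM=-1, mMAL=1), subs="mFUM", pros="mMAL", mods=list(I("mCIT"))),
 list(id="SDH", pathway="tca", form="mm_rev", r=3,
      st=c(mSUC=-1, mFUM=1), subs="mSUC", pros="mFUM",
      mods=list(I("mOAA"), I("mMAL"))),
 list(id="SCS", pathway="tca", form="haldane", r=2,
      st=c(mSCoA=-1, mADP=-1, mSUC=1, mATP=1), subs=c("mSCoA","mADP"),
      pros=c("mSUC","mATP")),
 list(id="AKGDH", pathway="tca", form="mm_irr",
      st=c(mAKG=-1, mSCoA=1), subs="mAKG", pros="mSCoA",
      mods=list(K("mNAD"), I("mNADH"), I("mSCoA"), A("mADP"), I("mATP"))),
 list(id="IDH", pathway="tca", form="mwc",
      st=c(mICIT=-1, mAKG=1), subs="mICIT", pros="mAKG",
      mwc=c(n=2, L0=3, c=0.01),
      mods=list(K("mNAD"), AA("mADP"), AI("mATP"), I("mNADH"))),
 list(id="ACO", pathway="tca", form="mm_rev", r=1.05,
      st=c(mCIT=-1, mICIT=1), subs="mCIT", pros="mICIT"),
 list(id="CS", pathway="tca", form="mm_irr",
      st=c(mOAA=-1, mAcCoA=-1, mCIT=1), subs=c("mOAA","mAcCoA"), pros="mCIT",
      mods=list(I("mCIT"), I("mATP"), I("mSCoA"), I("mNADH"))),
 list(id="PDH", pathway="tca", form="mm_irr",
      st=c(mPYR=-1, mAcCoA=1), subs="mPYR", pros="mAcCoA",
      mods=list(K("mNAD"), I("mAcCoA"), I("mNADH"), I("mATP"))),
 list(id="PC", pathway="tca", form="mm_irr",
      st=c(mPYR=-1, mATP=-1, mOAA=1, mADP=1), subs=c("mPYR","mATP"),
      pros=c("mOAA","mADP"), mods=list(A("mAcCoA"), I("mOAA"), I("mADP"))),
 ## ---- transport / shuttles / oxidative ATP ----
 list(id="MPC", pathway="shuttle", form="carrier", keq=1,
      st=c(PYR=-1, mPYR=1), subs="PYR", pros="mPYR", mods=list(I("LAC"))),
 list(id="MALAKG", pathway="shuttle", form="haldane", r=4,
      st=c(MAL=-1, mAKG=-1, mMAL=1, AKG=1), subs=c("MAL","mAKG"),
      pros=c("mMAL","AKG")),
 list(id="ASPGLU", pathway="shuttle", form="mm_irr",
      st=c(mASP=-1, GLU=-1, ASP=1, mGLU=1), subs=c("mASP","GLU"),
      pros=c("ASP","mGLU"), mods=list(I("ASP"), I("mGLU"))),
 list(id="CITMAL", pathway="shuttle", form="haldane", r=1.5,
      st=c(mCIT=-1, MAL=-1, CIT=1, mMAL=1), subs=c("mCIT","MAL"),
      pros=c("CIT","mMAL")),
 list(id="MALPi", pathway="shuttle", form="haldane", r=5, kmfac=0.3,
      st=c(mMAL=-1, Pi=-1, MAL=1, mPi=1), subs=c("mMAL","Pi"),
      pros=c("MAL","mPi")),
 list(id="ACL", pathway="shuttle", form="mm_irr",
      st=c(CIT=-1, ATP=-1, OAA=1, ADP=1), subs=c("CIT","ATP"),
      pros=c("OAA","ADP"), mods=list(I("ADP"), I("OAA"), I("AMP"))),
 list(id="OXPHOS", pathway="energetics", form="mm_irr",
      st=c(ADP=-1, mMAL=-1/15, ATP=1, mOAA=1/15), subs="ADP", pros="ATP",
      km=c(Ka_GSH=2.1, Ka_mMAL=0.2), mods=list(A("GSH"), A("mMAL"), K("Pi"), I("ATP")))
)

## --------------------------------------------------- parameter assembly
cval <- function(sp) max(conc[[sp]], 1e-3)

build_reaction <- function(d) {
  p <- list()
  add_km <- function(ids) for (s in ids) p[[paste0("Km_", s)]] <<- cval(s)
  if (d$form %in% c("mm_irr", "mm_rev")) add_km(c(d$subs,
    if (d$form == "mm_rev") d$pros))
  if (d$form == "haldane") add_km(c(d$subs, d$pros))
  if (d$form == "bibi_rev") {
    p$Kia <- cval(d$subs[1]); p$Kib <- cval(d$subs[2]); p$Kmb <- cval(d$subs[2])
    p$Kip <- cval(d$pros[1]); p$Kiq <- cval(d$pros[2]); p$Kmq <- cval(d$pros[2])
    p$Kd_AQ <- 10 * cval(d$subs[1]) * cval(d$pros[2])
    p$Kd_BP <- 10 * cval(d$subs[2]) * cval(d$pros[1])
  }
  if (d$form == "carrier") {
    p$Kms <- cval(d$subs[1]); p$Kmp <- cval(d$pros[1])
    p$Keq <- d$keq; p$alpha <- 1
  }
  if (d$form == "mwc") {
    add_km(d$subs)
    p$n <- unname(d$mwc[["n"]]); p$L0 <- unname(d$mwc[["L0"]])
    p$c <- unname(d$mwc[["c"]])
  }
  for (m in d$mods %||% list()) {
    x <- cval(m$species)
    p[[switch(m$type,
              inh = paste0("Ki_", m$species),
              act = paste0("Ka_", m$species),
              cof = paste0("Km_", m$species),
              allo_inh = paste0("Ki_", m$species),
              allo_act = paste0("Ka_", m$species))]] <-
      switch(m$type, inh = 3 * x, act = 0.5 * x, cof = 0.5 * x,
             allo_inh = 2 * x, allo_act = 1 * x)
  }
  if (!is.null(d$kmfac))
    for (nm in paste0("Km_", c(d$subs, d$pros)))
      if (!is.null(p[[nm]])) p[[nm]] <- p[[nm]] * d$kmfac
  for (nm in names(d$km %||% c())) p[[nm]] <- unname(d$km[[nm]])

  rx <- list(id = d$id, pathway = d$pathway, form = d$form,
             akt_modulated = isTRUE(d$akt),
             explicit_vr = d$form %in% c("mm_rev", "bibi_rev", "ma_rev"),
             stoich = d$st, subs = d$subs, pros = d$pros,
             modifiers = d$mods %||% list(), params = p)

  ## Keq for Haldane forms: baseline mass-action ratio times displacement r
  if (d$form == "haldane") {
    gamma <- prod(conc[d$pros]) / prod(conc[d$subs])
    rx$params$Keq <- gamma * d$r
  }

  ## velocity calibration at the baseline state
  target <- phi[[d$id]]
  if (d$id == "AK") {
    Ffwd <- 2e-03; Rrev <- 2.1333e-03  # net -4e-5, near equilibrium: ATP-producing at baseline
    vF1 <- rate_law_flux(rx, conc, 1, 0)
    vR1 <- -rate_law_flux(rx, conc, 0, 1)
    rx$params$Vf <- Ffwd / vF1
    rx$params$Vr <- Rrev / vR1
    rx$params$Veq <- rx$params$Vf / rx$params$Vr
  } else if (rx$explicit_vr) {
    vF1 <- rate_law_flux(rx, conc, 1, 0)
    vR1 <- -rate_law_flux(rx, conc, 0, 1)
    Ffwd <- target * d$r / (d$r - 1)
    Rrev <- Ffwd - target
    rx$params$Vf <- Ffwd / vF1
    rx$params$Vr <- Rrev / vR1
    rx$params$Veq <- rx$params$Vf / rx$params$Vr
  } else {
    v1 <- rate_law_flux(rx, conc, 1, 0)
    stopifnot(v1 > 0)
    rx$params$Vf <- (d$excess %||% 1) * target / v1
  }
  rx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
reactions <- lapply(rx_def, build_reaction)

## -------------------------------------------------------------- checks
stopifnot(length(species) == 46 + 7 + 4)
stopifnot(sum(vapply(species, function(s) s$type == "dynamic", TRUE)) == 46)
stopifnot(length(reactions) == 53)
nvel <- sum(vapply(reactions, function(r) 1 + r$explicit_vr, 0))
npar <- sum(vapply(reactions, function(r) length(r$params), 0))
cat("velocities:", nvel, "  total parameters:", npar, "\n")
stopifnot(nvel == 71)
if (npar != 372) stop("parameter inventory is ", npar, ", expected 372")

## baseline residual check: S v should be ~0 for dynamic species
sv <- setNames(numeric(length(ic1)), names(ic1))
for (r in reactions) {
  v <- rate_law_flux(r, conc, r$params$Vf, r$params$Vr %||% 0)
  for (s in names(r$stoich))
    if (s %in% names(sv)) sv[s] <- sv[s] + r$stoich[[s]] * v
}
cat("max |S v| over dynamic species at baseline:",
    signif(max(abs(sv)), 3), "\n")
print(sort(abs(sv), decreasing = TRUE)[1:8])

## -------------------------------------------------------------- output
cfg <- list(
  metadata = list(
    name = "pdac-central-metabolism",
    version = "1.0",
    description = paste(
      "Reference kinetic network of pancreatic cancer cell metabolism:",
      "glycolysis, glutaminolysis, TCA cycle, pentose phosphate pathway and",
      "mitochondrial shuttles. Reconstructed from the published source-model",
      "families; rate-law forms and constants are a calibrated approximation,",
      "not a byte-level copy of any published supplementary implementation."),
    units = list(concentration = "mM", time = "min", flux = "mM/min")),
  akt = list(basal = 0.2, span = 0.8),
  growth = list(alpha_atp = 7e-4, alpha_glc = 1e-4, alpha_gln = 3e-4,
                alpha_d = 1.2e-4, k_ap = 10, k_gc = 0.5, k_gn = 2, K_CC = 100),
  panel = c("G6P", "F6P", "G3P", "3PG", "PEP", "PYR", "LAC", "CIT", "AKG",
            "SUC", "FUM", "MAL", "ASP", "GLU"),
  defaults = list(media_glc = 35, media_gln = 6, t_obs = 1440,
                  duration = 7200, kd_reference = "GOT1", kd_alpha = 0.85,
                  lhs_n = 100, fit_subsample = 50,
                  correlation_threshold = 0.95),
  species = species,
  reactions = lapply(reactions, function(r) {
    list(id = r$id, pathway = r$pathway, form = r$form,
         akt_modulated = r$akt_modulated, explicit_vr = r$explicit_vr,
         stoich = as.list(r$stoich),
         substrates = as.list(r$subs), products = as.list(r$pros),
         modifiers = r$modifiers,
         params = lapply(r$params, function(x) signif(x, 8)))
  }))

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
yaml::write_yaml(cfg, "inst/extdata/pdac_network.yaml", precision = 8)

## Table of initial-condition bounds (mM)
bounds <- rbind(
  c("GLC",2.5,14), c("ATP",0.014,14), c("G6P",0.0061,2.1), c("ADP",0.0026,4.8),
  c("F6P",3.4e-4,0.84), c("FBP",0.0085,0.45), c("DHAP",0.0029,1.2),
  c("G3P",8e-4,1.2), c("NAD",0.018,2.2), c("13BPG",8e-4,0.12),
  c("3PG",0.0084,0.49), c("2PG",0.0056,0.06), c("PEP",0.0018,0.38),
  c("PYR",0.012,14), c("LAC",0.08,73), c("AMP",3.6e-5,3.4),
  c("6PG",0.0032,0.011), c("Ru5P",0.0094,0.078), c("Xyl5P",8e-5,0.019),
  c("R5P",0.003,0.022), c("E4P",8e-5,0.27), c("S7P",0.0065,0.081),
  c("NADP",0.0037,0.44), c("GSH",0.099,3.4), c("mPYR",0.012,14),
  c("mAcCoA",1.7e-4,0.17), c("mCIT",0.0064,1.2), c("mICIT",0.01,0.056),
  c("mAKG",0.0058,0.023), c("mSCoA",0.16,3.0), c("mSUC",0.17,2.8),
  c("mFUM",0.017,0.22), c("mMAL",0.096,2.4), c("mOAA",0.096,2.4),
  c("mASP",0.23,7.8), c("mGLU",0.0056,6.6), c("ASP",0.23,7.8),
  c("GLU",0.0056,6.6), c("OAA",0.096,2.4), c("MAL",0.096,2.4),
  c("AKG",0.0057,0.023), c("CIT",0.0064,1.2), c("GLN",0.16,5.6),
  c("NADH",8e-4,0.1), c("NADPH",9.6e-4,0.069), c("GSSG",0.1,1.1))
bounds <- data.frame(metabolite = bounds[,1],
                     lower = as.numeric(bounds[,2]),
                     upper = as.numeric(bounds[,3]))
stopifnot(nrow(bounds) == 46, all(bounds$lower > 0),
          all(bounds$lower <= bounds$upper),
          setequal(bounds$metabolite, names(ic1)))
write.csv(bounds, "inst/extdata/ic_bounds.csv", row.names = FALSE)

vic <- data.frame(metabolite = names(ic1), ic1 = unname(ic1),
                  ic2 = unname(ic2[names(ic1)]))
write.csv(vic, "inst/extdata/validated_ic.csv", row.names = FALSE)
cat("wrote inst/extdata/{pdac_network.yaml, ic_bounds.csv, validated_ic.csv}\n")
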