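---
title: "Secure SNP panels with encrypted K-mers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secure SNP panels with encrypted K-mers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerlock)
```

## The problem

A hospital owns a SNP panel: a curated set of disease-associated residues,
each a single-nucleotide variant with known reference and alternate alleles
and surrounding (flanking) sequence. A patient owns targeted-sequencing
reads. Both parties want the assay result — which panel alleles the reads
support — without the patient revealing raw sequence and without the
hospital revealing the panel content. kmerlock implements a two-party
scheme for this: the patient chunks reads into K-mers, encodes them as
indicator vectors and encrypts them under a lattice (RLWE) homomorphic
scheme; the hospital evaluates an equality-test circuit against its
plaintext panel K-mer codes and returns encrypted per-SNP match counts;
only the patient can decrypt. Aligning encrypted sequences is infeasible,
but testing equality of short fixed-length K-mers is not — so the whole
design reduces genotyping to exact K-mer matching, and the scientific work
is in making exact matching safe.

## Panel preprocessing

Residues whose flanked regions share sequence would force very long K-mers,
so pairs are resolved first (`preprocess_panel()`):

* an identical shared stretch of credible length — at least
  `full_overlap_cutoff` (100 bp, where the chance of an identical 100 bp
  overlap under a uniform base model, `overlap_chance(100)`, is below
  1e-59) and at most `max_overlap` (150 bp, the span a short read can
  bridge) — merges the two residues into one entity with an extended
  sequence;
* a shared stretch with any mismatch, or one longer than `max_overlap`,
  keeps one residue of the pair (a seeded coin flip) and logs the other in
  the discard table;
* identical overlaps shorter than the cutoff are treated as chance
  similarity and left alone.

Candidates are processed in (chrom, pos) order with a seeded RNG, so runs
are reproducible, and the residue count is conserved: every input residue
ends up in exactly one entity or in the discard log.

## K-mer design and the Point Deviation Tolerance

`kmerize_panel()` slides a stride-1 window over every allele version of
each entity. Windows covering a residue position form set A, labelled by
(residue, allele); all remaining windows of all versions form the
deduplicated background set B. A match against a set-A K-mer then certifies
the residue's allele — provided the K-mers are unambiguous. A *point
deviation* is any single-base departure from the panel's expected sequence
(somatic or germline variation, or a sequencing error in general settings).
The Point Deviation Tolerance (PDT) generalises uniqueness to a Hamming
separation requirement (`check_pdt_conditions()`):

1. every cross-locus pair within A is at Hamming distance > PDT, and
2. every A-by-B pair is at Hamming distance > PDT.

If a read K-mer carries at most PDT deviations from its true locus, it can
never equal another locus's panel K-mer, so cross-locus false positives are
impossible by construction. `find_min_k()` returns the smallest K in
`[PDT + 1, k_cap]` passing both conditions (distances are bounded by K, so
no shorter K can pass) and reports the violating pairs at K − 1. Minimal K
is non-decreasing in PDT and in panel size; both trends are verified by the
test suite on seeded panels.

Two points the conditions leave open were fixed as package policy. First,
the ref- and alt-allele windows at one locus differ by exactly one base, so
a literal reading of condition 1 would fail every panel at PDT ≥ 1;
same-locus pairs (identical entity and window start) are therefore exempt —
distinguishing those two K-mers is the assay's purpose, and a deviation
that converts one into the other changes the genotype itself rather than
creating a cross-locus confusion. Second, set B is built from the windows
of *both* allele versions of every entity, not only the reference
sequence: patient reads legitimately contain alt-allele background windows,
and those must not collide with any SNP-covering K-mer either.

## Encoding and encryption

K-mers are read as quaternary integers (A, C, G, T → 0, 1, 2, 3, first base
most significant; `to_quaternary_int("GACT")` is 135). Encoding a whole
K-mer as one integer would need a huge plaintext space, so K-mers are split
into B blocks of L bases (`split_blocks()`, final block right-padded with
`A`, panel codes padded identically). For a batch of N user K-mers, block
b of all of them is encoded into one binary vector with slot
`K^(n)[b] * N + n` set for user K-mer n (`build_indicator_vectors()`); the
map is injective because n < N. The slot dimension is the smallest power of
two that *covers* the index range `4^L * N` (`choose_slots()`): the
indicator index can reach `4^L * N − 1`, so rounding is upward — the
tightest power of two consistent with every index fitting.

The backend (`rlwe_backend()`) is a BGV-style exact integer scheme on the
power-of-two cyclotomic ring `Z_q[X]/(X^n + 1)`: secret and error
polynomials from a narrow distribution (ternary secret, discrete Gaussian
errors with sigma = 3.2), public key `b = −a·s + p·e`, encryption
`(m + v·b + p·e0, v·a + p·e1)`, decryption by centred reduction mod q then
mod p. Choosing the plaintext modulus p prime with `p = 1 (mod 2n)` splits
the plaintext ring into n evaluation slots; the package packs messages into
one Galois orbit of n/2 slots (the orbit of the element 5), so slotwise
addition and multiplication correspond to ring operations — an exact
isomorphism, tested directly — and the automorphism `X -> X^(5^r)` followed
by a key switch rotates the slots cyclically by r. Exact integer batching
was chosen over approximate fixed-point packing deliberately: every message
in this protocol is a binary indicator or a small count, so exact
arithmetic preserves the semantics bit-for-bit and lets the test suite
demand *identical* results from the encrypted and plaintext backends rather
than results up to rounding.

The ciphertext modulus is a product of 30-bit NTT-friendly primes (RNS
representation; every modular product fits a 64-bit word). Multiplication
produces a component on `s^2`, and rotations produce one on `s(X^g)`; both
return to `s` by key switching with per-prime CRT-digit decomposition. The
published multiplication rule is schematic about how the evaluation key
scales the `s^2` term, so the package adopts this standard digit
decomposition and enforces the contract `dec(mult(c1, c2)) = m1 * m2` by
test rather than by matching the schematic symbol-for-symbol.

Noise is tracked as a heuristic central-limit-style log2 bound: fresh
ciphertexts start near `log2(p) + log2(sigma^2 * sqrt(n))`, key switches
add a floor term proportional to the 30-bit digit width, and each
multiplication level roughly doubles the bound plus a `sqrt(n)` convolution
factor. A parameter preset (`rlwe_params(n_ring, depth)`) chooses the
number of primes so the worst protocol depth fits with >= 20 bits of
headroom; any operation that would cross the budget aborts before results
can corrupt silently, and decryption additionally measures the true payload
magnitude and fails loudly above 0.45 of the modulus. The presets
(n = 256–4096) are sized for desk-scale experiments and are **not**
production-secure parameters; selecting production parameters is out of
scope.

## The equality-test protocol

`match_panel()` runs the four protocol steps once per (residue, allele)
group of panel K-mers, so the output is a per-SNP readout rather than one
aggregate count — the result the patient actually needs:

1. rotate the block-b user ciphertext by `N * K_ref[b]`: batch slot n now
   flags agreement of block b with the panel K-mer;
2. multiply the B rotated ciphertexts componentwise: slot n flags full
   K-mer equality;
3. sum over the group's K-mers: slot n counts matches (0 or 1 under the
   design guarantee that panel K-mers are distinct; a duplicated panel
   K-mer shows up as a 2, a failure mode the tests exercise);
4. rotate-and-add over the batch so slot 0 carries the group's total count.

Only the patient's data is encrypted; the hospital contributes plaintext
block codes, the public, evaluation and rotation keys, and never sees a
decryption. Batches beyond N user K-mers are processed independently and
their per-group sums are added homomorphically before step 4. Internally
the step-2 products are kept unrelinearized (component lists grow along the
product tree) and each group is relinearized once after the step-3 sum —
about a third of the key switches of the naive order, with identical
decrypted results (the exported `step2_block_product()` / `step3_sum()`
keep the textbook contracts and are tested against oracles). The exact
plaintext backend implements the same operation contract on clear vectors
mod p and serves both as the correctness oracle for the encrypted path and
as a fast mode for large simulations.

`decrypt_report()` turns slot-0 counts into calls: ref / alt when only one
allele accrues counts, `het` when both do, and `no_coverage` when neither
does. A no-coverage residue is exactly the detectable false-negative state:
the assay cannot have missed silently, because a present residue with
usable reads must produce at least one matching K-mer.

## The false-negative risk model

Cross-locus false positives are controlled by PDT, but a deviation *near a
panel SNP* can erase all of that residue's matching K-mers — a false
negative. With a catalog of mutation positions, `count_close_pairs()`
counts same-chromosome pairs within a window (32 bp by default, one K-mer
span; the boundary is inclusive, `|Δpos| <= window`, a convention the
package fixes and documents since "within a window" is ambiguous at the
edge). If c of the `choose(n, 2)` catalog pairs are close, a panel of N
residues collides with probability

P = 1 − (1 − c / C(n, 2))^C(N, 2),

computed in log space (`fn_risk()`). With the published catalog constants
(116,607 mutations; 1,308 close pairs of 6,798,537,921) the risk stays
below 0.1% through N = 100. Reported percentages are rounded half-up to two
significant figures, which is how the package prints them in its risk
table; recomputing the catalog from raw tumour data is out of scope, so the
constants enter as inputs.

## The synthetic-data generator

`simulate_panel()` and `simulate_reads()` reproduce the targeted-sequencing
conditions the package is tested under: residues with 650 bp flanks per
side, paired 151 bp reads at mean depth 10, zero sequencing error, and a
50% per-residue chance that the planted allele is the substitution. Flanks
are i.i.d. uniform bases standing in for sampled coding sequence: K-design
and protocol correctness depend only on sequence distinctness, which
uniform sequence stresses conservatively at these lengths (real genomes
contain repeats, which would push minimal K upward — so absolute K values
from the simulator are not comparable to genome-derived panels, while all
monotone trends are). The planted allele is drawn per residue and all of a
residue's reads carry it; read-level mixtures (true heterozygosity) would
change expected counts but not the match logic, and the `het` call path is
tested directly. Paired fragments draw their outer insert uniformly between
twice the read length and 500 bp (capped by the entity): a fixed insert
would leave deterministic coverage gaps on short test entities, and the
insert distribution is immaterial to K-mer matching. `inject_deviations()`
adds seeded point substitutions with distance constraints — at most PDT per
read so every K-mer carries at most PDT deviations, or at one exact
distance d from the residue for the false-negative geometry law (a single
deviation at distance d leaves exactly min(d, window limit) of a read's
residue-covering K-mers matching).

Everything is deterministic given the seed, through a single R RNG stream
per operation. What the generator does **not** emulate: genomic repeats and
homology, indels and structural variants, sequencing-error models, base
quality variation, GC bias, and diploid allele balance. Passing tests on
synthetic data therefore demonstrate the correctness of the scheme's logic
and arithmetic under its stated assumptions, not calling performance on
real libraries.

## Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to exercise every code path
at desk scale: operation-level backend equivalence at n = 256 over 200
randomized trials; the full encrypted protocol on a 10-residue panel with
short (25 bp) flanks and 36 bp single-end reads at n = 2048 (block size
L = 3, batches of N = 16); genotype recovery under the full study
conditions (650 bp flanks, paired 151 bp reads, depth 10) on the exact
plaintext backend with N = 512; and PDT soundness over 50 seeded trials of
4-residue panels. For the encrypted full-protocol run the generator
redraws a panel (bumping the seed) if its minimal K exceeds 12, keeping
the block count — hence multiplicative depth — within the depth-2 preset;
this is a feasibility filter applied before any result is computed.
Degenerate inputs are defined errors: K longer than an entity, residues
closer than K to an entity end, rotation amounts without keys, slot demand
beyond ring capacity, counts approaching the plaintext modulus, and
mismatched parameter fingerprints all abort with explicit messages.

## Limitations

The scheme reveals K and the panel's group count to the patient by
construction, and per-SNP results to the patient by design. The parameter
presets favour testability over security margin. Minimal K values on
uniform synthetic panels underestimate genome-derived panels. The risk
model treats catalog mutations as exchangeable and panels as uniform draws
from the catalog; it is a design guideline, not a clinical error bound.
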