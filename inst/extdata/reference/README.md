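# Reference coordinate files

The Elp2 superposition check compares two public crystal structures of
yeast Elp2 over their common Calpha atoms. The coordinate files are not
redistributed with this package; to run the comparison, download them
from the Protein Data Bank and place them here as:

- `5m2n.pdb` — Elp2 at 2.8 A (https://www.rcsb.org/structure/5M2N)
- `4xfv.pdb` — Elp2 at 3.2 A (https://www.rcsb.org/structure/4XFV)

Then:

```r
a <- read_structure(system.file("extdata/reference/5m2n.pdb", package = "rigidem"))
b <- read_structure(system.file("extdata/reference/4xfv.pdb", package = "rigidem"))
a$atoms$chain <- b$atoms$chain <- "A"
superpose_rmsd(a, b)
```
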