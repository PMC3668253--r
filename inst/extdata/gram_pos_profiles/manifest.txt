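# Gram-positive surface-motif profile manifest.
# One profile per line: display-name  accession(s)  description.
# The display name is what appears in evidence details, e.g. hmm(LPxTG).
# Drop additional profile HMMs into this directory and list them here to
# extend the scan.
LPxTG            PF00746              cell-wall sorting signal
GW_repeat        SF0040855,SF0040856,SF0040857  GW repeat domains
PG_binding_1     PF01471,PF08823,PF09374  peptidoglycan binding (type 1)
Choline_binding  PF01473              choline binding repeat
LysM             PF01476              LysM domain
CW_binding_2     PF04122              cell-wall binding (type 2)
SLH              PF04122              S-layer homology domain (accession shared with CW_binding_2 in the source listing)
NLPC_P60         PF00877              NLPC/P60 cell-wall associated domain
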