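# Default residue alphabet: 58 core residues supported on both the NRP and
# the BGC side. One residue per line; an optional second column may carry a
# background frequency. Users may replace this file with their own list.
# 20 proteinogenic residues
ala
arg
asn
asp
cys
gln
glu
gly
his
ile
leu
lys
met
phe
pro
ser
thr
trp
tyr
val
# common nonribosomal monomers
orn
dab
dap
hpg
dhpg
pgl
bht
hty
hse
pip
hyp
mpro
aad
abu
aib
dhb
sal
kyn
cit
cap
end
ival
nva
nle
bala
blys
ahp
choi
adda
dha
dhab
hleu
hasn
horn
allothr
alloile
cysa
3mglu
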