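site_id	PE-like	PET-like	PP-like	PVC-like	PC-like	PS-like	Amide-like
SSV	absent	absent	absent	absent	absent	absent	present
SMTL	present	present	present	present	present	present	present
TL	present	present	present	present	absent	absent	present
C	absent	present	absent	present	absent	present	absent
SPC	present	present	present	present	present	absent	present
SAC	present	present	present	present	absent	absent	present
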