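gene	hgvs_c	hgvs_p
CEBPA	c.985_988dupGAAC	p.Gln330Argfs*74
GATA2	c.1061C>T	p.Thr354Met
TERT	c.1445delA	p.His482Profs*27
FANCA	c.2505-1G>T	
SBDS	c.258+2T>C	
SBDS	c.183_184delinsCT	p.Lys62X
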