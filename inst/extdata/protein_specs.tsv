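PROTEIN	LOC	G0	UBIQ	INDUCER	ACTIVATOR	INACTIVATOR	FUNCTION
p27	N	high	KPC;SCF(Skp2);APC(Cdc20)	constitutive			inhibits cyclins--prevent S
Rb	N	high		constitutive;E2F inhibits	Cdc14*	cycD/Cdk4or6;cycE/Cdk2;cycA/Cdk2;cycA/Cdk1;cycB/Cdk1	inhibits E2F
cycD	N	0	SCF(Skp2);APC(Cdc20)*	mitogen;B-Myb*	Cdk4or6		activates Cdk4or6 kinase; inactivates APC(Cdh1)
Cdk2	N	high		constitutive;E2F	cycE;cycA;Cdc25A		kinase--phosphorylates RC--allows DNA replication
cycE	N	0	SCF(Fbw7)--on Cdk2;SCF(Skp2)--free	E2F	Cdk2	p27	activates Cdk2 kinase
B-Myb	N	0	SCF(Skp2)--free	E2F;B-Myb	cycA/Cdk2;cycE/Cdk2*		TF for cycD, Cdk1, Plk1, DNA pol, B-Myb, TF-grow, others
NF-Y	N	0	?	constitutive;E2F	cycA/Cdk2;cycE/Cdk2*	Cdc14*	TF for cycA, cycB, Cdk1, Cdc25C, TF-grow
E2F	N	0	SCF(Skp2);APC(Cdc20)*	constitutive;E2F;B-Myb inhibits**		Rb;cycB/Cdk1;cycA/Cdk2**;cycA/Cdk1**;cycD/Cdk4or6**	TF for cycE, cycA, Rb, Cdk1, Cdk2, E2F, Cdc25A, DNA pol, others
cycA	N	0	APC(Cdh1);SCF(Skp2)**;APC(Cdc20)**	E2F;NF-Y;mitogen;adhesion**	Cdk2;Cdc25A;Cdk1;Cdc25B;Cdc25C	p27 (for cycA/Cdk2);Wee1 (for cycA/Cdk1)	activates Cdk2 and Cdk1 kinases
SCF	CN	0	APC(Cdh1)	constitutive	Skp2;Btrc;Fbw7		ubiquitinase (requires subunit)
Skp2	N	0	auto (when no Emi1 or Wee1);APC(Cdh1)	constitutive	SCF		ubiquitinase subunit for p27, E2F, RC, TF-grow, B-Myb, free cycE, cycA, cycD, others
Btrc	C	0	auto (when no p27, cycE, E2F, or RC);APC(Cdh1);APC(Cdc20)	E2F	SCF		ubiquitinase subunit for Emi1, Cdc25A (sometimes), Wee1, others
Fbw7	N	0	auto (when no cycE, TF-grow**, or RC**)	E2F	SCF		ubiquitinase subunit for cycE, TF-grow, RC**
TF-grow	N	0	SCF(Skp2);SCF(Fbw7) (not while on DNA)*	mitogen;Skp2;B-Myb			TF for cell growth
RC	N	0	SCF(Fbw7)**;SCF(Skp2);APC(Cdh1)	E2F	cycE/Cdk2;cycA/Cdk2;cycD/Cdk4or6	cycA/Cdk1;p27	DNA replication complex
DNApol	N	0		E2F;B-Myb;NF-Y*;inhibits itself*	RC		DNA polymerase
Wee1	C	high	SCF(Btrc)	constitutive	Cdc14	cycA/Cdk2**;cycA/Cdk1**;cycB/Cdk1**;Plk1	kinase--prevents Cdk1 activation
cycB	CN	0	APC(Cdc20);APC(Cdh1)	E2F;B-Myb;NF-Y	Cdk1		activate Cdk1 kinase
Cdk1	CN	high*		E2F;B-Myb;NF-Y;constitutive	cycA;cycB;B-Myb;NF-Y;Plk1;Cdc25A;Cdc25B;Cdc25C	Wee1;Cdc14	kinase--activates APC(Cdc20)
Cdc25C	CN	high		constitutive;NF-Y**	cycB/Cdk1;Plk1;cycA/Cdk1*	Cdc14	phosphatase--activates cycB/Cdk1
Plk1	C	0	APC(Cdh1)	E2F;TF-grow	cycB/Cdk1;cycA/Cdk1*		kinase--activates Cdc25C; deactivates Emi1, Wee1; translocates cycA/Cdk1, cycB/Cdk1, Cdc25C, and Plk1 to nucleus
Emi1	CN	0	SCF(Btrc);SCF(Skp2)*	E2F		cycB/Cdk1;cycA/Cdk1*	inhibits Cdh1, Cdc20
APC	N	high		constitutive	Cdh1;Cdc20		ubiquitinase (requires subunit)
Cdh1	N	high	auto (when no Skp2, cycA, cycB, Cdc25A, Plk1, RC, Cdc20, SCF*, p27**)	constitutive	APC;Cdc14	Emi1;cycA/Cdk2;cycB/Cdk1;cycD/Cdk4or6;cycE/Cdk2	ubiquitinase subunit--maintains G0, G1
Cdc20	N	0	APC(Cdh1)	constitutive	APC;cycB/Cdk1;cycA/Cdk1*	Emi1;Cdc14	ubiquitinase subunit for Securin, cycB, cycA
Cdc14	N	high		constitutive	Plk1*	Securin	phosphatase--ends M--activates p27, Wee1, Cdh1; deactivates Cdc25A, Cdc25B, Cdc25C
Cdc25A	N	0	APC(Cdh1);SCF(Btrc)*	constitutive;E2F;TF-grow	cycE/Cdk2;cycA/Cdk2;cycA/Cdk1*;cycB/Cdk1*	Cdc14	phosphatase--activates cycE/Cdk2, cycA/Cdk2
Cdc25B	C	0	APC(Cdh1)*;SCF(Btrc)*	E2F*;TF-grow*	TF-grow**;cycA/Cdk1*;cycB/Cdk1*	Cdc14	phosphatase--activates cycA/Cdk1, cycB/Cdk1*
Securin	N	0	APC(Cdc20)	E2F			keeps separase from destroying chromatid cohesion
cycC	N	high		constitutive	Cdk8;Cdc14*	mitogen*	inhibits RNA pol
KPC	N	high		constitutive	mitogen		ubiquitinase for p27
RNApol	N	high		constitutive;TF-grow*	mitogen*	cycC/Cdk8;APC(Cdc20)*	transcription
eIF-4	C	high		constitutive	mRNA		initiates translation
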