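taxon_id	name	rank	status	accepted_id	kingdom	phylum	class	order	family	genus	species
K1	Animalia	kingdom	valid	K1	Animalia						
K2	Plantae	kingdom	valid	K2	Plantae						
P1	Thalassozoa	phylum	valid	P1	Animalia	Thalassozoa					
P2	Virentophyta	phylum	valid	P2	Plantae	Virentophyta					
C1	Petrozoa	class	valid	C1	Animalia	Thalassozoa	Petrozoa				
C2	Limnozoa	class	valid	C2	Animalia	Thalassozoa	Limnozoa				
C3	Viridopsida	class	valid	C3	Plantae	Virentophyta	Viridopsida				
O1	Petralia	order	valid	O1	Animalia	Thalassozoa	Petrozoa	Petralia			
O2	Limnalia	order	valid	O2	Animalia	Thalassozoa	Limnozoa	Limnalia			
O3	Viridales	order	valid	O3	Plantae	Virentophyta	Viridopsida	Viridales			
F1	Petridae	family	valid	F1	Animalia	Thalassozoa	Petrozoa	Petralia	Petridae		
F2	Granidae	family	valid	F2	Animalia	Thalassozoa	Petrozoa	Petralia	Granidae		
F3	Limnidae	family	valid	F3	Animalia	Thalassozoa	Limnozoa	Limnalia	Limnidae		
F4	Viridaceae	family	valid	F4	Plantae	Virentophyta	Viridopsida	Viridales	Viridaceae		
G1	Petrus	genus	valid	G1	Animalia	Thalassozoa	Petrozoa	Petralia	Petridae	Petrus	
G2	Granus	genus	valid	G2	Animalia	Thalassozoa	Petrozoa	Petralia	Granidae	Granus	
G3	Limnus	genus	valid	G3	Animalia	Thalassozoa	Limnozoa	Limnalia	Limnidae	Limnus	
G4	Limnella	genus	valid	G4	Animalia	Thalassozoa	Limnozoa	Limnalia	Limnidae	Limnella	
G5	Virida	genus	valid	G5	Plantae	Virentophyta	Viridopsida	Viridales	Viridaceae	Virida	
G6	Viridella	genus	valid	G6	Plantae	Virentophyta	Viridopsida	Viridales	Viridaceae	Viridella	
S1	Petrus albus	species	valid	S1	Animalia	Thalassozoa	Petrozoa	Petralia	Petridae	Petrus	Petrus albus
S2	Petrus niger	species	valid	S2	Animalia	Thalassozoa	Petrozoa	Petralia	Petridae	Petrus	Petrus niger
S3	Petrus rubra	species	valid	S3	Animalia	Thalassozoa	Petrozoa	Petralia	Petridae	Petrus	Petrus rubra
S4	Petrus parvus	species	valid	S4	Animalia	Thalassozoa	Petrozoa	Petralia	Petridae	Petrus	Petrus parvus
S5	Granus magna	species	valid	S5	Animalia	Thalassozoa	Petrozoa	Petralia	Granidae	Granus	Granus magna
S6	Granus minuta	species	valid	S6	Animalia	Thalassozoa	Petrozoa	Petralia	Granidae	Granus	Granus minuta
S7	Limnus lenta	species	valid	S7	Animalia	Thalassozoa	Limnozoa	Limnalia	Limnidae	Limnus	Limnus lenta
S8	Limnus acuta	species	valid	S8	Animalia	Thalassozoa	Limnozoa	Limnalia	Limnidae	Limnus	Limnus acuta
S9	Limnus plana	species	valid	S9	Animalia	Thalassozoa	Limnozoa	Limnalia	Limnidae	Limnus	Limnus plana
S10	Limnella gracilis	species	valid	S10	Animalia	Thalassozoa	Limnozoa	Limnalia	Limnidae	Limnella	Limnella gracilis
S11	Limnella robusta	species	valid	S11	Animalia	Thalassozoa	Limnozoa	Limnalia	Limnidae	Limnella	Limnella robusta
S12	Virida laeta	species	valid	S12	Plantae	Virentophyta	Viridopsida	Viridales	Viridaceae	Virida	Virida laeta
S13	Virida fusca	species	valid	S13	Plantae	Virentophyta	Viridopsida	Viridales	Viridaceae	Virida	Virida fusca
S14	Viridella tenuis	species	valid	S14	Plantae	Virentophyta	Viridopsida	Viridales	Viridaceae	Viridella	Viridella tenuis
S15	Viridella crassa	species	valid	S15	Plantae	Virentophyta	Viridopsida	Viridales	Viridaceae	Viridella	Viridella crassa
Y1	Vetustus primus	species	synonym	S1	Animalia	Thalassozoa	Petrozoa	Petralia	Petridae	Petrus	Petrus albus
Y2	Vetustus secundus	species	synonym	S3	Animalia	Thalassozoa	Petrozoa	Petralia	Petridae	Petrus	Petrus rubra
Y3	Priscus notus	species	synonym	S6	Animalia	Thalassozoa	Petrozoa	Petralia	Granidae	Granus	Granus minuta
Y4	Priscus vetus	species	synonym	S10	Animalia	Thalassozoa	Limnozoa	Limnalia	Limnidae	Limnella	Limnella gracilis
Y5	Antiqua nota	species	synonym	S13	Plantae	Virentophyta	Viridopsida	Viridales	Viridaceae	Virida	Virida fusca
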