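code	depth_m	utm_zone	utm_e	utm_n	altitude_m	toponym	province	install_date	recovery_date	orientation	massif
SSD-1	1	30T	4081	45204	1606	Cancho del Rio Peces	Segovia	2015-05-20	2015-09-17	North	Siete Picos - La Mujer Muerta
SSD-1(0.5)	0.5	30T	4081	45204	1606	Cancho del Rio Peces	Segovia	2015-05-20	2015-09-17	North	Siete Picos - La Mujer Muerta
SSD-2	1	30T	4100	45166	1818	Corrales de la Majada Minguete	Segovia	2015-05-20	2015-09-17	Northeast	Siete Picos - La Mujer Muerta
SSD-2(0.5)	0.5	30T	4100	45166	1818	Corrales de la Majada Minguete	Segovia	2015-05-20	2015-09-17	Northeast	Siete Picos - La Mujer Muerta
SSD-3	1	30T	4068	45192	1622	Umbria de la Mujer Muerta	Segovia	2015-05-21	2015-09-17	North	Siete Picos - La Mujer Muerta
SSD-3(0.5)	0.5	30T	4068	45192	1622	Umbria de la Mujer Muerta	Segovia	2015-05-21	2015-09-17	North	Siete Picos - La Mujer Muerta
SSD-4	1	30T	4056	45181	1685	Majada Conejo	Segovia	2015-05-21	2015-09-17	Northwest	Siete Picos - La Mujer Muerta
SSD-4(0.5)	0.5	30T	4056	45181	1685	Majada Conejo	Segovia	2015-05-21	2015-09-17	Northwest	Siete Picos - La Mujer Muerta
SSD-11	1	30T	4108	45161	1876	Cerro Ventoso	Madrid	2015-06-09	2015-09-17	East	Siete Picos - La Mujer Muerta
SSD-5	1	30T	4166	45159	1923	Arroyo Seco	Segovia	2015-05-27	2015-09-22	Northwest	Puerto de los Cotos - Puerto de Navacerrada
SSD-6	1	30T	4179	45185	1787	La Pedriza	Segovia	2015-05-27	2015-09-22	Northwest	Puerto de los Cotos - Puerto de Navacerrada
SSD-7	1	30T	4185	45229	1994	Majada Hambrienta	Segovia	2015-06-02	2015-09-17	Northwest	Montes Carpetanos
SSD-8	1	30T	4190	45231	2071	Majada Aranguez	Segovia	2015-06-02	2015-09-17	Northwest	Montes Carpetanos
SSD-9	1	30T	4187	45211	2208	Dos Hermanas	Madrid	2015-06-03	2015-10-05	East	Montes Carpetanos
SSD-10	1	30T	4191	45213	2049	Hoya de la Laguna Grande	Madrid	2015-06-03	2015-10-05	East	Montes Carpetanos
SSD-16	1	30T	4334	45389	1956	Las Revueltas - Los Horcos	Segovia	2015-06-23	2015-10-07	West	Montes Carpetanos
SSD-17	1	30T	4347	45414	1976	Pena del Buitre	Segovia	2015-06-23	2015-10-07	Northwest	Montes Carpetanos
SSD-18	1	30T	4373	45438	1885	Los Loberos	Segovia	2015-06-23	2015-10-07	Northwest	Montes Carpetanos
SSD-19	1	30T	4224	45307	1866	La Gelecha - La Flecha	Madrid	2015-06-24	2015-10-06	Southeast	Montes Carpetanos
SSD-20	1	30T	4226	45332	1937	Cerro de Navahonda	Segovia	2015-06-24	2015-10-06	Northeast	Montes Carpetanos
SSD-21	1	30T	4211	45274	1891	El Paredon	Madrid	2015-06-24	2015-10-06	Northeast	Montes Carpetanos
SSD-22	1	30T	4304	45376	1995	Alto del Puerto	Segovia	2015-06-24	2015-09-22	North	Montes Carpetanos
SSD-23	1	30T	4288	45367	2144	Circo del Pico Nevero	Madrid	2015-06-25	2015-10-06	Sourtheast	Montes Carpetanos
SSD-24	1	30T	4274	45357	2042	Penacabra	Madrid	2015-06-25	2015-10-22	East	Montes Carpetanos
SSD-25	1	30T	4249	45407	1731	Arroyo del Charco (La Cepa)	Segovia	2015-07-02	2015-10-22	Northwest	Montes Carpetanos
TSP-1	0.8	30T	4314	45376	1780	Puerto de Navafria	Segovia	2015-06-24	2015-09-22	North	Montes Carpetanos
TSP-2	0.8	30T	4314	45376	1780	Puerto de Navafria	Segovia	2015-06-24	2015-09-22	North	Montes Carpetanos
SSD-12	1	30T	4180	45138	2102	Collado del Piornal	Madrid	2015-06-09	2015-09-22	North	Cuerda Larga and associated mountainous complex
SSD-13	1	30T	4179	45135	2113	Los Almorchones - Las Buitreras	Madrid	2015-06-10	2015-09-22	Southwest	Cuerda Larga and associated mountainous complex
SSD-14	1	30T	4274	45224	1406	El Purgatorio	Madrid	2015-06-18	2015-10-05	West	Cuerda Larga and associated mountainous complex
SSD-15	1	30T	4273	45224	1375	Hueco de los Angeles	Madrid	2015-06-18	2015-10-05	Northeast	Cuerda Larga and associated mountainous complex
SSD-26	1	30T	4309	45186	1890	La Najarra - Cuatro Calles	Madrid	2015-07-02	2015-10-30	East	Cuerda Larga and associated mountainous complex
SSD-27	1	30T	4270	45185	2101	Bailaderos	Madrid	2015-07-02	2015-10-30	North	Cuerda Larga and associated mountainous complex
SSD-28	1	30T	4193	45164	2156	Collado de Valdemartin	Madrid	2015-07-03	2015-11-06	North	Cuerda Larga and associated mountainous complex
SSD-29	1	30T	4211	45168	2301	Cabeza de Hierro Mayor Menor	Madrid	2015-07-03	2015-11-06	Crest	Cuerda Larga and associated mountainous complex
SSD-30	1	30T	4227	45170	2233	Collado de Pena Vaqueros (Loma de Pandasco)	Madrid	2015-07-03	2015-11-06	Crest	Cuerda Larga and associated mountainous complex
SSD-31	1	30T	4288	45184	1946	Collado de la Najarra	Madrid	2015-07-09	2015-10-22	North	Cuerda Larga and associated mountainous complex
SSD-32	1	30T	4285	45187	1948	Arroyo de La Najarra	Madrid	2015-07-09	2015-10-22	Northeast	Cuerda Larga and associated mountainous complex
SSD-33	1	30T	4286	45188	1819	Arroyo de La Najarra	Madrid	2015-07-09	2015-10-22	North	Cuerda Larga and associated mountainous complex
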